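# Allele classification from amplicon sequences: global alignment against
# homoeologue references, indel/substitution calling with left-aligned
# normalization, coding-consequence prediction on the spliced CDS, and the
# six-allele fertility rule (sterile only when no functional allele remains).

#' Global affine-gap alignment of an amplicon against a reference
#'
#' Optimal Needleman-Wunsch alignment with affine gaps (via
#' \code{Biostrings::pairwiseAlignment}); a gap of length L costs
#' \code{-(gap_open + L * gap_extend)} under the default
#' \code{\link{alignScoring}}.
#'
#' @param query,reference sequences (character or XString), non-empty.
#' @param scoring an \code{\link{alignScoring}} list.
#' @return list: \code{query}, \code{reference} (aligned strings with
#'   \code{"-"} gaps) and \code{score}.
#' @export
alignGlobal <- function(query, reference, scoring = alignScoring()) {
  q <- as.character(query); r <- as.character(reference)
  if (!nzchar(q) || !nzchar(r))
    stop("alignGlobal requires non-empty sequences")
  aln <- pairwise_aln(q, r, scoring)
  list(query = as.character(Biostrings::alignedPattern(aln)),
       reference = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Assign an amplicon to its homoeologue
#'
#' The amplicon is aligned against each of the three reference regions; the
#' best-scoring reference wins when it beats the runner-up by at least
#' \code{min_margin} score units, otherwise the call is \code{"ambiguous"}.
#' The default margin of 2 requires at least one diagnostic difference under
#' the default scoring.
#'
#' @param amplicon query sequence.
#' @param triplet_refs named \code{DNAStringSet} (names = subgenomes) of
#'   reference amplicon regions.
#' @param min_margin minimal winning margin (score units).
#' @param scoring an \code{\link{alignScoring}} list.
#' @return list: \code{call} (subgenome or \code{"ambiguous"}) and
#'   \code{scores}.
#' @export
assignHomoeologue <- function(amplicon, triplet_refs, min_margin = 2,
                              scoring = alignScoring()) {
  stopifnot(length(triplet_refs) >= 2, !is.null(names(triplet_refs)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  scores <- vapply(seq_along(triplet_refs), function(i)
    Biostrings::pairwiseAlignment(
      pattern = as.character(amplicon),
      subject = as.character(triplet_refs[[i]]),
      type = "global", substitutionMatrix = mat,
      gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
      scoreOnly = TRUE), numeric(1))
  names(scores) <- names(triplet_refs)
  ord <- order(scores, decreasing = TRUE)
  call <- if (scores[ord[1]] - scores[ord[2]] >= min_margin)
    names(scores)[ord[1]] else "ambiguous"
  list(call = call, scores = scores)
}

#' Call variants from a global alignment
#'
#' Walks the alignment columns, merges adjacent gap columns of the same type
#' into single indel events, reports substitutions per column, and
#' left-aligns indels (gaps shifted maximally 5'-ward on the reference).
#' Positions are 1-based reference forward coordinates; a deletion's
#' \code{pos} is its first deleted base, an insertion's \code{pos} is the
#' reference base after which the inserted sequence sits (0 = before the
#' first base).
#'
#' @param alignment output of \code{\link{alignGlobal}}.
#' @return data.frame: pos, ref, alt, length_change.
#' @export
callVariants <- function(alignment) {
  q <- strsplit(alignment$query, "")[[1]]
  r <- strsplit(alignment$reference, "")[[1]]
  stopifnot(length(q) == length(r))
  vars <- list(); k <- 0L
  rpos <- 0L
  i <- 1L
  n <- length(q)
  while (i <= n) {
    if (r[i] != "-" && q[i] != "-") {
      rpos <- rpos + 1L
      if (r[i] != q[i]) {
        k <- k + 1L
        vars[[k]] <- data.frame(pos = rpos, ref = r[i], alt = q[i],
                                length_change = 0L, stringsAsFactors = FALSE)
      }
      i <- i + 1L
    } else if (q[i] == "-") {            # deletion run
      j <- i
      while (j <= n && q[j] == "-") j <- j + 1L
      del <- paste(r[i:(j - 1L)], collapse = "")
      k <- k + 1L
      vars[[k]] <- data.frame(pos = rpos + 1L, ref = del, alt = "",
                              length_change = -nchar(del),
                              stringsAsFactors = FALSE)
      rpos <- rpos + nchar(del)
      i <- j
    } else {                             # insertion run
      j <- i
      while (j <= n && r[j] == "-") j <- j + 1L
      ins <- paste(q[i:(j - 1L)], collapse = "")
      k <- k + 1L
      vars[[k]] <- data.frame(pos = rpos, ref = "", alt = ins,
                              length_change = nchar(ins),
                              stringsAsFactors = FALSE)
      i <- j
    }
  }
  out <- if (k) do.call(rbind, vars) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               length_change = integer(), stringsAsFactors = FALSE)
  leftAlignVariants(out, gsub("-", "", alignment$reference))
}

#' Left-align indel variants against the reference
#'
#' Shifts each indel maximally 5'-ward: a deletion moves left while the base
#' preceding it equals its last deleted base; an insertion moves left while
#' its last inserted base equals the reference base at the insertion point.
#' Substitutions are untouched. This is the package's normalization
#' convention; both simulated truth and called variants pass through it so
#' representations are comparable.
#'
#' @param variants variant data.frame (pos, ref, alt, length_change).
#' @param refseq reference sequence (character).
#' @return the normalized variant data.frame, sorted by position.
#' @export
leftAlignVariants <- function(variants, refseq) {
  refseq <- as.character(refseq)
  if (!nrow(variants)) return(variants)
  for (i in seq_len(nrow(variants))) {
    lc <- variants$length_change[i]
    if (lc < 0) {                       # deletion
      p <- variants$pos[i]; L <- -lc
      while (p > 1 &&
             substring(refseq, p - 1, p - 1) ==
             substring(refseq, p + L - 1, p + L - 1))
        p <- p - 1L
      variants$pos[i] <- p
      variants$ref[i] <- substring(refseq, p, p + L - 1)
    } else if (lc > 0) {                # insertion
      p <- variants$pos[i]; S <- variants$alt[i]; L <- nchar(S)
      while (p >= 1 &&
             substring(S, L, L) == substring(refseq, p, p)) {
        S <- paste0(substring(refseq, p, p), substring(S, 1, L - 1))
        p <- p - 1L
      }
      variants$pos[i] <- p
      variants$alt[i] <- S
    }
  }
  variants[order(variants$pos), , drop = FALSE]
}

#' Apply variants to a reference sequence
#'
#' Inverse of \code{\link{callVariants}} on non-overlapping variants:
#' substitutions replace bases, deletions remove \code{ref}, insertions add
#' \code{alt} after \code{pos}.
#'
#' @param refseq reference sequence (character).
#' @param variants variant data.frame.
#' @return the edited sequence (character).
#' @export
applyVariants <- function(refseq, variants) {
  s <- as.character(refseq)
  if (!nrow(variants)) return(s)
  ord <- order(variants$pos, decreasing = TRUE)
  for (i in ord) {
    p <- variants$pos[i]; lc <- variants$length_change[i]
    if (lc == 0) {
      substring(s, p, p) <- variants$alt[i]
    } else if (lc < 0) {
      s <- paste0(substring(s, 1, p - 1), substring(s, p - lc))
    } else {
      s <- paste0(substring(s, 1, p), variants$alt[i], substring(s, p + 1))
    }
  }
  s
}

# genomic positions covered by a variant (deletion span; substitutions one
# base; insertions the two flanking bases p, p+1)
variant_span <- function(v) {
  if (v$length_change < 0) IRanges(v$pos, v$pos - v$length_change - 1L)
  else if (v$length_change > 0) IRanges(v$pos, v$pos + 1L)
  else IRanges(v$pos, v$pos)
}

intron_ranges <- function(model) {
  ex <- model@exons
  if (length(ex) < 2) return(IRanges())
  IRanges(head(end(ex), -1) + 1L, tail(start(ex), -1) - 1L)
}

splice_critical_ranges <- function(model) {
  intr <- intron_ranges(model)
  if (!length(intr)) return(IRanges())
  c(IRanges(start(intr), pmin(start(intr) + 1L, end(intr))),
    IRanges(pmax(end(intr) - 1L, start(intr)), end(intr)))
}

#' Predict the coding consequence of an allele's variants
#'
#' Variants are projected onto the spliced CDS. Rules, in order: variants
#' destroying the first or last two bases of an intron are splice-disrupting
#' (not functional); loss of the CDS start codon's first base by a deletion
#' is loss of function; a net in-CDS length change that is not a multiple of
#' 3 is a frameshift (not functional); an in-frame change is translated and
#' scanned -- a stop before the final codon is a premature stop (not
#' functional), otherwise in-frame indels and missense changes are
#' functional by default (a strict mode marks in-frame deletions above
#' \code{max_inframe_aa} amino acids non-functional). Variants touching no
#' exon are noncoding and functional.
#'
#' @param variants variant data.frame (left-aligned, reference forward
#'   coordinates).
#' @param model the allele's \linkS4class{GeneModel}.
#' @param refseq the reference genomic sequence the coordinates refer to.
#' @param strict mark large in-frame deletions non-functional.
#' @param max_inframe_aa threshold (amino acids) for the strict mode.
#' @return list: \code{consequence} (one of wild_type, synonymous,
#'   missense_inframe, inframe_indel, frameshift, premature_stop,
#'   splice_disrupting, noncoding) and \code{functional} (logical).
#' @export
predictConsequence <- function(variants, model, refseq, strict = FALSE,
                               max_inframe_aa = 30) {
  refseq <- as.character(refseq)
  if (!nrow(variants))
    return(list(consequence = "wild_type", functional = TRUE))
  spans <- do.call(c, lapply(seq_len(nrow(variants)), function(i)
    variant_span(variants[i, ])))
  crit <- splice_critical_ranges(model)
  if (length(crit)) {
    hit_crit <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      if (v$length_change > 0) {
        # an insertion disrupts only when it splits a critical dinucleotide
        any(v$pos == start(crit) & start(crit) < end(crit))
      } else {
        any(IRanges::overlapsAny(variant_span(v), crit))
      }
    }, logical(1))
    if (any(hit_crit))
      return(list(consequence = "splice_disrupting", functional = FALSE))
  }
  cdsr <- model@cds
  if (!length(cdsr)) {
    return(list(consequence = "noncoding", functional = TRUE))
  }
  start_base <- if (model@strand == "+") min(start(cdsr)) else max(end(cdsr))
  start_lost <- any(variants$length_change < 0 &
    IRanges::overlapsAny(spans[variants$length_change < 0],
                         IRanges(start_base, start_base)))
  # net length change inside the CDS
  net <- 0L
  cds_touched <- FALSE
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$length_change < 0) {
      ol <- sum(width(IRanges::pintersect(
        rep(variant_span(v), length(cdsr)), cdsr,
        resolve.empty = "start.x")))
      net <- net - ol
      if (ol > 0) cds_touched <- TRUE
    } else if (v$length_change > 0) {
      inside <- IRanges::overlapsAny(IRanges(v$pos, v$pos), cdsr) &&
        IRanges::overlapsAny(IRanges(v$pos + 1L, v$pos + 1L), cdsr) &&
        # both flanks in the same CDS segment
        any(start(cdsr) <= v$pos & end(cdsr) >= v$pos + 1L)
      if (inside) {
        net <- net + v$length_change
        cds_touched <- TRUE
      }
    } else {
      if (IRanges::overlapsAny(variant_span(v), cdsr)) cds_touched <- TRUE
    }
  }
  if (!cds_touched)
    return(list(consequence = "noncoding", functional = TRUE))
  if (net %% 3L != 0L)
    return(list(consequence = "frameshift", functional = FALSE))
  if (start_lost) {
    return(list(consequence = "inframe_indel", functional = FALSE))
  }
  # in-frame: build the edited spliced CDS and translate
  edit <- project_variants_on_cds(variants, model, refseq)
  aa <- as.character(Biostrings::translate(DNAString(edit$cds),
                                           if.fuzzy.codon = "X"))
  stops <- gregexpr("\\*", aa, fixed = FALSE)[[1]]
  premature <- stops[1] != -1 && any(stops < nchar(aa))
  if (premature)
    return(list(consequence = "premature_stop", functional = FALSE))
  has_indel <- any(variants$length_change != 0)
  if (has_indel) {
    functional <- !(strict && net < 0 && (-net / 3) > max_inframe_aa)
    return(list(consequence = "inframe_indel", functional = functional))
  }
  ref_aa <- as.character(Biostrings::translate(extractCDS(model, refseq),
                                               if.fuzzy.codon = "X"))
  if (identical(aa, ref_aa))
    list(consequence = "synonymous", functional = TRUE)
  else list(consequence = "missense_inframe", functional = TRUE)
}

# apply variants in CDS space; returns list(cds = edited spliced CDS string)
project_variants_on_cds <- function(variants, model, refseq) {
  cdsr <- model@cds
  gpos <- unlist(lapply(seq_along(cdsr), function(i)
    seq(start(cdsr)[i], end(cdsr)[i])))
  cds_fwd <- strsplit(paste(substring(refseq, start(cdsr), end(cdsr)),
                            collapse = ""), "")[[1]]
  keep <- rep(TRUE, length(gpos))
  ins_after <- rep("", length(gpos))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$length_change == 0) {
      idx <- match(v$pos, gpos)
      if (!is.na(idx)) cds_fwd[idx] <- v$alt
    } else if (v$length_change < 0) {
      del <- seq(v$pos, v$pos - v$length_change - 1L)
      keep[gpos %in% del] <- FALSE
    } else {
      idx <- match(v$pos, gpos)
      if (!is.na(idx) && idx < length(gpos) && gpos[idx + 1L] == v$pos + 1L)
        ins_after[idx] <- paste0(ins_after[idx], v$alt)
    }
  }
  pieces <- ifelse(keep, cds_fwd, "")
  out <- paste0(pieces, ins_after, collapse = "")
  if (model@strand == "-") out <- revcomp(out)
  list(cds = out)
}

#' Fertility call from a six-allele genotype
#'
#' A plant is male-sterile if and only if none of its six alleles (two per
#' homoeologue) is functional; a single functional (e.g. wild-type or
#' in-frame) allele anywhere maintains fertility.
#'
#' @param allele_calls data.frame with exactly 6 rows for one plant and a
#'   logical \code{functional} column.
#' @return \code{"sterile"} or \code{"fertile"}.
#' @export
callFertility <- function(allele_calls) {
  if (nrow(allele_calls) != 6L)
    stop("a plant genotype needs exactly 6 allele calls, got ",
         nrow(allele_calls))
  if (sum(allele_calls$functional) == 0L) "sterile" else "fertile"
}

#' Genotype a cohort of plants from amplicon sequences
#'
#' Amplicon record ids of the form \code{"plant|homoeologue|allele"} are
#' taken as pre-assigned; otherwise ids must be \code{"plant"} or
#' \code{"plant|..."} and each amplicon is assigned to a homoeologue by
#' alignment score (ambiguous records are excluded with a warning). A plant
#' supplying a single sequence for a homoeologue is treated as homozygous
#' there (logged). Each allele is aligned to its homoeologue reference,
#' variants are called and normalized, and the coding consequence decides
#' the functional flag; plant fertility follows the six-allele rule.
#'
#' @param amplicons named \code{DNAStringSet} of per-allele amplicons.
#' @param triplet the reference \linkS4class{HomoeologueTriplet}.
#' @param min_margin homoeologue-assignment margin (see
#'   \code{\link{assignHomoeologue}}).
#' @param scoring an \code{\link{alignScoring}} list.
#' @param strict,max_inframe_aa passed to \code{\link{predictConsequence}}.
#' @return list: \code{alleles} (data.frame: plant_id, homoeologue,
#'   allele_index, n_variants, net_length_change, consequence, functional)
#'   and \code{plants} (data.frame: plant_id, n_functional, fertility).
#' @export
genotypePlants <- function(amplicons, triplet, min_margin = 2,
                           scoring = alignScoring(), strict = FALSE,
                           max_inframe_aa = 30) {
  refs <- tripletSeqs(triplet)
  models <- tripletModels(triplet)
  ids <- names(amplicons)
  parts <- strsplit(ids, "|", fixed = TRUE)
  pre <- vapply(parts, function(p)
    length(p) == 3L && p[2] %in% names(refs), logical(1))
  recs <- data.frame(idx = seq_along(amplicons),
                     plant_id = vapply(parts, `[`, "", 1),
                     homoeologue = ifelse(pre,
                                          vapply(parts, `[`, "", 2),
                                          NA_character_),
                     allele_index = ifelse(pre,
                                           suppressWarnings(as.integer(
                                             vapply(parts, `[`, "", 3))),
                                           NA_integer_),
                     stringsAsFactors = FALSE)
  n_ambig <- 0L
  for (i in which(!pre)) {
    as_ <- assignHomoeologue(amplicons[[i]], refs, min_margin, scoring)
    if (as_$call == "ambiguous") {
      n_ambig <- n_ambig + 1L
    } else {
      recs$homoeologue[i] <- as_$call
    }
  }
  if (n_ambig)
    warning(n_ambig, " amplicon(s) ambiguous between homoeologues; excluded")
  recs <- recs[!is.na(recs$homoeologue), , drop = FALSE]
  rows <- list(); k <- 0L
  n_homozygous_assumed <- 0L
  for (pid in unique(recs$plant_id)) {
    for (sg in c("A", "B", "D")) {
      sub <- recs[recs$plant_id == pid & recs$homoeologue == sg, ,
                  drop = FALSE]
      if (!nrow(sub)) next
      if (nrow(sub) == 1L) {
        sub <- rbind(sub, sub)
        sub$allele_index <- 1:2
        n_homozygous_assumed <- n_homozygous_assumed + 1L
      }
      if (any(is.na(sub$allele_index))) sub$allele_index <- seq_len(nrow(sub))
      for (j in seq_len(min(nrow(sub), 2L))) {
        refchr <- as.character(refs[[sg]])
        aln <- alignGlobal(amplicons[[sub$idx[j]]], refchr, scoring)
        vars <- callVariants(aln)
        cons <- predictConsequence(vars, models[[sg]], refchr,
                                   strict = strict,
                                   max_inframe_aa = max_inframe_aa)
        k <- k + 1L
        rows[[k]] <- data.frame(
          plant_id = pid, homoeologue = sg,
          allele_index = sub$allele_index[j],
          n_variants = nrow(vars),
          net_length_change = sum(vars$length_change),
          consequence = cons$consequence, functional = cons$functional,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    stop("no amplicon could be assigned to a homoeologue; ",
         "check the references or provide pre-assigned record ids")
  alleles <- do.call(rbind, rows)
  plants <- do.call(rbind, lapply(split(alleles, alleles$plant_id),
    function(d) data.frame(plant_id = d$plant_id[1],
                           n_functional = sum(d$functional),
                           fertility = callFertility(d),
                           stringsAsFactors = FALSE)))
  plants <- plants[order(plants$plant_id), ]
  rownames(plants) <- NULL
  if (n_homozygous_assumed)
    message(n_homozygous_assumed, " homoeologue(s) had a single amplicon; ",
            "treated as homozygous")
  list(alleles = alleles, plants = plants)
}

#' Expected T1 classes after rescue with wild-type pollen
#'
#' A sterile (or any) mother crossed to a wild-type pollen donor transmits
#' one of her two alleles per homoeologue; the paternal allele is wild type
#' everywhere, so every T1 plant carries at least one functional allele per
#' homoeologue and is fertile under the six-allele rule.
#'
#' @param mother_alleles data.frame with 6 rows (homoeologue, allele_index,
#'   functional).
#' @return list: \code{classes} (data.frame homoeologue, maternal_allele
#'   class, expected_fraction) and \code{fertility} (always
#'   \code{"fertile"}).
#' @export
predictRescueProgeny <- function(mother_alleles) {
  stopifnot(nrow(mother_alleles) == 6L)
  out <- list()
  for (sg in c("A", "B", "D")) {
    f <- mother_alleles$functional[mother_alleles$homoeologue == sg]
    stopifnot(length(f) == 2L)
    cls <- table(ifelse(f, "wild_type/Wt", "mutant/Wt")) / 2
    out[[sg]] <- data.frame(homoeologue = sg,
                            t1_class = names(cls),
                            expected_fraction = as.numeric(cls),
                            stringsAsFactors = FALSE)
  }
  list(classes = do.call(rbind, out), fertility = "fertile")
}
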