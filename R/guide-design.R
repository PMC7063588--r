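# Cas9 guide selection for homoeologue triplets: pattern scan for
# 5'-[A|G](N)20 GG-3' on both strands, strict conservation across all three
# homoeologues, exon overlap, restriction-site screenability at the blunt
# cut, and ranking by distance to the CDS start with promoter-slot
# assignment.

#' Default restriction enzyme panel
#'
#' Common palindromic 6-cutters used for digest-based edit screening; the
#' table is user-overridable (name, site).
#'
#' @return data.frame with columns \code{name}, \code{site}.
#' @export
defaultEnzymes <- function() {
  data.frame(
    name = c("EcoRI", "BamHI", "HindIII", "PstI", "SalI", "XbaI", "SpeI",
             "KpnI", "SacI", "SphI", "NcoI", "NdeI", "EcoRV", "DraI"),
    site = c("GAATTC", "GGATCC", "AAGCTT", "CTGCAG", "GTCGAC", "TCTAGA",
             "ACTAGT", "GGTACC", "GAGCTC", "GCATGC", "CCATGG", "CATATG",
             "GATATC", "TTTAAA"),
    stringsAsFactors = FALSE)
}

#' Guide design configuration
#'
#' @param protospacer_len protospacer length (20).
#' @param first_base_alternatives allowed protospacer first bases (the
#'   pattern is 5'-[A|G](N)20 GG-3'; A-initial guides suit U3-type
#'   promoters, G-initial suit U6-type).
#' @param cut_offset_from_pam blunt-cut offset in bp 5' of the PAM (3:
#'   between protospacer positions 17 and 18).
#' @param enzymes restriction enzyme table (name, site); see
#'   \code{\link{defaultEnzymes}}.
#' @param require_exon_overlap drop guides whose protospacer overlaps no
#'   exon (default TRUE; "at least partially in an exon" means a 1-bp
#'   overlap suffices).
#' @param n_select number of guides to select (default 4, one per promoter
#'   slot).
#' @param promoter_slots ordered promoter slots (default OsU3, OsU6, TaU3,
#'   TaU6).
#' @return a \code{GuideConfig} list.
#' @export
guideConfig <- function(protospacer_len = 20,
                        first_base_alternatives = c("A", "G"),
                        cut_offset_from_pam = 3,
                        enzymes = defaultEnzymes(),
                        require_exon_overlap = TRUE,
                        n_select = 4,
                        promoter_slots = c("OsU3", "OsU6", "TaU3", "TaU6")) {
  stopifnot(protospacer_len >= 17, nrow(enzymes) >= 1,
            all(c("name", "site") %in% names(enzymes)))
  structure(list(protospacer_len = as.integer(protospacer_len),
                 first_base_alternatives = first_base_alternatives,
                 cut_offset_from_pam = as.integer(cut_offset_from_pam),
                 enzymes = enzymes,
                 require_exon_overlap = require_exon_overlap,
                 n_select = as.integer(n_select),
                 promoter_slots = promoter_slots),
            class = "GuideConfig")
}

scan_one_strand <- function(s, plen) {
  # overlapping matches of [A|G] N{plen-1} + NGG over unambiguous bases
  pat <- sprintf("(?=([AG][ACGT]{%d}GG))", plen)
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

#' Scan a sequence for Cas9 target sites
#'
#' Every window of protospacer length + 3 on both strands whose first base
#' is A or G and whose final two bases are GG yields a raw candidate
#' (protospacer = the first 20 bases, PAM = the final 3). Windows containing
#' N are skipped. Minus-strand hits are reported in forward coordinates
#' (1-based closed window span) with strand \code{"-"}. \code{cut_after} is
#' the forward coordinate after which the blunt cut falls (3 bp 5' of the
#' PAM on the protospacer strand).
#'
#' @param seq sequence (character or XString), length >= 23.
#' @param config a \code{\link{guideConfig}}.
#' @return data.frame: protospacer, pam, strand, start, end, cut_after. An
#'   empty result is valid.
#' @export
findTargets <- function(seq, config = guideConfig()) {
  s <- toupper(as.character(seq))
  plen <- config$protospacer_len
  wlen <- plen + 3L
  empty <- data.frame(protospacer = character(), pam = character(),
                      strand = character(), start = integer(),
                      end = integer(), cut_after = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(s) < wlen) return(empty)
  rows <- list()
  fwd <- scan_one_strand(s, plen)
  if (length(fwd))
    rows$fwd <- data.frame(
      protospacer = substring(s, fwd, fwd + plen - 1L),
      pam = substring(s, fwd + plen, fwd + wlen - 1L),
      strand = "+", start = fwd, end = fwd + wlen - 1L,
      cut_after = fwd + plen - config$cut_offset_from_pam - 1L,
      stringsAsFactors = FALSE)
  rc <- revcomp(s)
  rev <- scan_one_strand(rc, plen)
  if (length(rev)) {
    # window at rc position j spans forward coordinates
    # [L - j - wlen + 2, L - j + 1]
    L <- nchar(s)
    fstart <- L - rev - wlen + 2L
    rows$rev <- data.frame(
      protospacer = substring(rc, rev, rev + plen - 1L),
      pam = substring(rc, rev + plen, rev + wlen - 1L),
      strand = "-", start = fstart, end = fstart + wlen - 1L,
      cut_after = fstart + config$cut_offset_from_pam + 2L,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  bad <- !substring(out$protospacer, 1, 1) %in% config$first_base_alternatives
  out <- out[!bad, , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all occurrences (1-based window starts and strands) of protospacer+NGG in
# a homoeologue sequence
find_hits <- function(proto, seqchr, config) {
  plen <- nchar(proto)
  hit_one <- function(s) {
    pat <- sprintf("(?=(%s[ACGT]GG))", proto)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m)
  }
  L <- nchar(seqchr)
  f <- hit_one(seqchr)
  r <- hit_one(revcomp(seqchr))
  out <- data.frame(start = integer(), end = integer(), strand = character(),
                    cut_after = integer(), stringsAsFactors = FALSE)
  wlen <- plen + 3L
  if (length(f))
    out <- rbind(out, data.frame(
      start = f, end = f + wlen - 1L, strand = "+",
      cut_after = f + plen - config$cut_offset_from_pam - 1L))
  if (length(r)) {
    fstart <- L - r - wlen + 2L
    out <- rbind(out, data.frame(
      start = fstart, end = fstart + wlen - 1L, strand = "-",
      cut_after = fstart + config$cut_offset_from_pam + 2L))
  }
  out
}

# spliced-CDS coordinate (1-based) of a genomic position; positions outside
# the CDS are clamped to the nearest CDS base
genomic_to_cds <- function(model, gpos) {
  cdsr <- model@cds
  stopifnot(length(cdsr) > 0)
  st <- start(cdsr); en <- end(cdsr); w <- width(cdsr)
  cum <- cumsum(c(0L, w))
  gpos <- min(max(gpos, min(st)), max(en))
  i <- max(which(st <= gpos))
  off <- min(gpos, en[i]) - st[i] + 1L
  pos_plus <- cum[i] + off
  if (model@strand == "+") pos_plus else sum(w) - pos_plus + 1L
}

#' Keep guides conserved across all three homoeologues
#'
#' A candidate survives when its exact protospacer, immediately followed by
#' an NGG PAM (the N is free), occurs in every homoeologue; candidates with
#' more than one such hit in any homoeologue are dropped as non-unique
#' (genotyping amplicons must be unambiguous). Per-homoeologue hit
#' coordinates, cut positions, exon overlap and spliced distance of the cut
#' to the CDS start are recorded.
#'
#' @param cands raw candidates from \code{\link{findTargets}}.
#' @param triplet a \linkS4class{HomoeologueTriplet} with A, B and D members.
#' @param config a \code{\link{guideConfig}}.
#' @return data.frame: one row per surviving candidate, with per-homoeologue
#'   columns \code{start_/end_/strand_/cut_after_/exon_overlap_/cds_dist_}
#'   suffixed by subgenome. Dropped non-unique candidates are reported via
#'   \code{message()}.
#' @export
filterConserved <- function(cands, triplet, config = guideConfig()) {
  models <- tripletModels(triplet)
  seqs <- tripletSeqs(triplet)
  stopifnot(all(c("A", "B", "D") %in% names(models)))
  keep <- logical(nrow(cands))
  extras <- vector("list", nrow(cands))
  n_nonunique <- 0L
  for (i in seq_len(nrow(cands))) {
    proto <- cands$protospacer[i]
    row <- list()
    ok <- TRUE
    for (sg in c("A", "B", "D")) {
      schr <- as.character(seqs[[sg]])
      hits <- find_hits(proto, schr, config)
      if (nrow(hits) != 1L) {
        if (nrow(hits) > 1L) n_nonunique <- n_nonunique + 1L
        ok <- FALSE
        break
      }
      m <- models[[sg]]
      proto_rng <- if (hits$strand == "+")
        IRanges(hits$start, hits$end - 3L)
      else IRanges(hits$start + 3L, hits$end)
      row[[paste0("start_", sg)]] <- hits$start
      row[[paste0("end_", sg)]] <- hits$end
      row[[paste0("strand_", sg)]] <- hits$strand
      row[[paste0("cut_after_", sg)]] <- hits$cut_after
      row[[paste0("exon_overlap_", sg)]] <-
        any(IRanges::overlapsAny(proto_rng, m@exons))
      row[[paste0("cds_dist_", sg)]] <-
        genomic_to_cds(m, hits$cut_after) - 1L
    }
    keep[i] <- ok
    if (ok) extras[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (n_nonunique)
    message(n_nonunique,
            " candidate(s) dropped as non-unique in a homoeologue")
  out <- cands[keep, , drop = FALSE]
  if (nrow(out)) out <- cbind(out, do.call(rbind, extras[keep]))
  rownames(out) <- NULL
  out
}

#' Keep guides overlapping an exon in every homoeologue
#'
#' "At least partially in an exon": a single base of protospacer-exon
#' overlap suffices, but it must hold in all three homoeologues.
#'
#' @param cands conserved candidates from \code{\link{filterConserved}}.
#' @return the filtered table.
#' @export
filterExonic <- function(cands) {
  if (!nrow(cands)) return(cands)
  ok <- cands$exon_overlap_A & cands$exon_overlap_B & cands$exon_overlap_D
  out <- cands[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep guides screenable by restriction digest at the cut site
#'
#' A guide is screenable when some enzyme's recognition sequence (or its
#' reverse complement) occurs within the 23-mer target window at a position
#' spanning the blunt cut (between protospacer positions 17 and 18): only
#' then does a cut-site indel destroy the site, enabling digest-based edit
#' screening. Matched enzymes are recorded (comma-separated).
#'
#' @param cands candidate table with a \code{protospacer} and \code{pam}
#'   column.
#' @param config a \code{\link{guideConfig}} with a non-empty enzyme table.
#' @return the filtered table with a \code{screenable_enzymes} column.
#' @export
filterRestrictionScreenable <- function(cands, config = guideConfig()) {
  if (!nrow(cands)) {
    cands$screenable_enzymes <- character(0)
    return(cands)
  }
  enz <- config$enzymes
  plen <- config$protospacer_len
  cut_lo <- plen - config$cut_offset_from_pam        # 17
  cut_hi <- cut_lo + 1L                              # 18
  hits <- character(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    window <- paste0(cands$protospacer[i], cands$pam[i])
    found <- character()
    for (j in seq_len(nrow(enz))) {
      for (site in unique(c(enz$site[j], revcomp(enz$site[j])))) {
        locs <- gregexpr(sprintf("(?=%s)", site), window, perl = TRUE)[[1]]
        if (locs[1] == -1) next
        ends <- locs + nchar(site) - 1L
        if (any(locs <= cut_lo & ends >= cut_hi)) {
          found <- c(found, enz$name[j])
          break
        }
      }
    }
    hits[i] <- paste(unique(found), collapse = ",")
  }
  cands$screenable_enzymes <- hits
  out <- cands[nzchar(hits), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank surviving guides and assign promoter slots
#'
#' Guides are sorted ascending by the worst-case (maximum over homoeologues)
#' spliced-transcript distance of the cut site from the CDS start, with ties
#' broken by lexicographically smaller protospacer. The top \code{n_select}
#' are returned with promoter slots assigned in order, preferring A-initial
#' protospacers for U3-type slots and G-initial for U6-type where possible.
#' When fewer candidates pass than slots exist, all are returned with a
#' warning that a promoter would have to be duplicated.
#'
#' @param cands fully filtered candidate table.
#' @param config a \code{\link{guideConfig}}.
#' @return the selected table with \code{rank_score} (bp) and
#'   \code{promoter_slot} columns.
#' @export
rankAndAssign <- function(cands, config = guideConfig()) {
  if (!nrow(cands)) {
    warning("no guide candidates passed all filters")
    cands$rank_score <- numeric(0)
    cands$promoter_slot <- character(0)
    return(cands)
  }
  score <- pmax(cands$cds_dist_A, cands$cds_dist_B, cands$cds_dist_D)
  ord <- order(score, cands$protospacer)
  sel <- head(ord, config$n_select)
  out <- cands[sel, , drop = FALSE]
  out$rank_score <- score[sel]
  if (nrow(out) < config$n_select)
    warning("only ", nrow(out), " guide(s) passed all filters for ",
            config$n_select, " promoter slots; a promoter would have to be ",
            "duplicated")
  slots <- config$promoter_slots[seq_len(min(nrow(out),
                                             length(config$promoter_slots)))]
  pref <- ifelse(grepl("U3", slots), "A", ifelse(grepl("U6", slots), "G", ""))
  assigned <- rep(NA_character_, nrow(out))
  taken <- logical(nrow(out))
  first <- substring(out$protospacer, 1, 1)
  for (k in seq_along(slots)) {
    cand_idx <- which(!taken & (pref[k] == "" | first == pref[k]))
    if (!length(cand_idx)) cand_idx <- which(!taken)
    if (!length(cand_idx)) break
    i <- cand_idx[1]   # candidates are already in rank order
    assigned[i] <- slots[k]
    taken[i] <- TRUE
  }
  out$promoter_slot <- assigned
  rownames(out) <- NULL
  out
}

#' Design guides for a homoeologue triplet end to end
#'
#' Pattern scan on the A-genome member, conservation across all three
#' homoeologues, exon overlap, restriction screenability at the cut, then
#' ranking and promoter-slot assignment.
#'
#' @param triplet a \linkS4class{HomoeologueTriplet} with A, B, D members.
#' @param config a \code{\link{guideConfig}}.
#' @return the selected guide table (see \code{\link{rankAndAssign}}).
#' @export
designGuides <- function(triplet, config = guideConfig()) {
  raw <- findTargets(tripletSeqs(triplet)[["A"]], config)
  cons <- filterConserved(raw, triplet, config)
  if (config$require_exon_overlap) cons <- filterExonic(cons)
  cons <- filterRestrictionScreenable(cons, config)
  rankAndAssign(cons, config)
}

#' Re-validate an emitted guide table
#'
#' Self-check pass over designed guides: pattern match (first base, PAM),
#' exactly one conserved hit per homoeologue, exon overlap everywhere, and a
#' cut-spanning enzyme site. Returns TRUE or stops with the first violation.
#'
#' @param guides output of \code{\link{designGuides}}.
#' @param triplet the triplet the guides were designed for.
#' @param config the \code{\link{guideConfig}} used.
#' @return TRUE (invisibly) when every guide re-validates.
#' @export
validateGuides <- function(guides, triplet, config = guideConfig()) {
  for (i in seq_len(nrow(guides))) {
    proto <- guides$protospacer[i]
    if (!substring(proto, 1, 1) %in% config$first_base_alternatives)
      stop("guide ", i, ": first base not in ",
           paste(config$first_base_alternatives, collapse = "/"))
    if (substring(guides$pam[i], 2, 3) != "GG")
      stop("guide ", i, ": PAM does not end in GG")
    for (sg in c("A", "B", "D")) {
      hits <- find_hits(proto, as.character(tripletSeqs(triplet)[[sg]]),
                        config)
      if (nrow(hits) != 1L)
        stop("guide ", i, ": not uniquely conserved in homoeologue ", sg)
      if (!guides[[paste0("exon_overlap_", sg)]][i])
        stop("guide ", i, ": no exon overlap in homoeologue ", sg)
    }
    if (!nzchar(guides$screenable_enzymes[i]))
      stop("guide ", i, ": no cut-spanning restriction site")
  }
  invisible(TRUE)
}

#' Write a guide report TSV and protospacer FASTA
#'
#' Coordinates in the report are 1-based closed, as computed.
#'
#' @param guides guide table from \code{\link{designGuides}}.
#' @param tsv_path report path.
#' @param fasta_path optional protospacer FASTA path.
#' @param header optional character vector of \code{#}-prefixed provenance
#'   lines to prepend.
#' @return invisibly, \code{tsv_path}.
#' @export
writeGuideReport <- function(guides, tsv_path, fasta_path = NULL,
                             header = NULL) {
  con <- file(tsv_path, "w")
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(guides, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (!is.null(fasta_path) && nrow(guides)) {
    pros <- DNAStringSet(guides$protospacer)
    names(pros) <- sprintf("guide_%02d_%s", seq_len(nrow(guides)),
                           ifelse(is.na(guides$promoter_slot), "unslotted",
                                  guides$promoter_slot))
    writeFastaRecords(pros, fasta_path)
  }
  invisible(tsv_path)
}
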