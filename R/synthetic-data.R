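# Synthetic hexaploid fixtures with known ground truth: a homoeologue-triplet
# generator, a negative-binomial stamen/pistil counts generator, and a
# Cas9-edited-cohort generator. Every generator is a pure function of
# (params, seed) via a local RNG stream.

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

with_local_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Parameters for the homoeologue-triplet simulator
#'
#' @param n_exons number of exons.
#' @param exon_len,intron_len integer ranges \code{c(min,max)} in bp for exon
#'   and intron lengths. Exon lengths are rounded down to codon multiples so
#'   the spliced CDS stays in frame.
#' @param flank_len UTR/flank length added on each side of the gene body.
#' @param divergence per-site substitution probability in [0, 0.5) applied
#'   independently to each homoeologue outside conserved windows.
#' @param conserved_windows list of 1-based closed \code{c(start,end)}
#'   intervals (genomic, within the gene sequence) forced identical across
#'   the three homoeologues.
#' @param planted_enzyme_sites list of \code{list(seq =, at =)} entries: a
#'   recognition sequence written into the ancestral gene at 1-based
#'   position \code{at} and kept conserved across homoeologues.
#' @param planted_guide_targets list of \code{list(at =, first_base =,
#'   enzyme =)} entries: a full 23-bp Cas9 target (first base A or G, an
#'   enzyme recognition site spanning the blunt cut, NGG PAM) written at
#'   1-based position \code{at} and kept conserved, so guide design has
#'   known positives. The window content avoids stop codons in every frame.
#' @param inter_homoeologue_indels logical; when TRUE small indels are also
#'   introduced between homoeologues (stress-test mode). Default FALSE so
#'   amplicon length differences are attributable to edits.
#' @param seed integer seed.
#' @return a \code{TripletSimParams} list.
#' @export
tripletSimParams <- function(n_exons = 3, exon_len = c(240, 360),
                             intron_len = c(80, 160), flank_len = 100,
                             divergence = 0.03,
                             conserved_windows = list(),
                             planted_enzyme_sites = list(),
                             planted_guide_targets = list(),
                             inter_homoeologue_indels = FALSE,
                             seed = 1L) {
  stopifnot(n_exons >= 1, divergence >= 0, divergence < 0.5,
            all(exon_len > 0), all(intron_len > 0), flank_len >= 0)
  structure(list(n_exons = n_exons, exon_len = exon_len,
                 intron_len = intron_len, flank_len = flank_len,
                 divergence = divergence,
                 conserved_windows = conserved_windows,
                 planted_enzyme_sites = planted_enzyme_sites,
                 planted_guide_targets = planted_guide_targets,
                 inter_homoeologue_indels = inter_homoeologue_indels,
                 seed = as.integer(seed)),
            class = "TripletSimParams")
}

# a 23-bp Cas9 target window (protospacer + NGG) whose cut site is spanned by
# the enzyme recognition sequence; content avoids T so no stop codon can
# arise in any frame inside the window
planted_target_seq <- function(first_base = "A", enzyme = "GAATTC") {
  stopifnot(first_base %in% c("A", "G"), nchar(enzyme) == 6)
  filler <- paste(sample(c("A", "C"), 13, replace = TRUE), collapse = "")
  paste0(first_base, filler, toupper(enzyme), "CGG")
}

random_codons <- function(n) {
  # codons without stop codons
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- paste(sample(BASES, 3, replace = TRUE), collapse = "")
      if (!cod %in% STOPS) break
    }
    out[i] <- cod
  }
  out
}

# Repair in-frame premature stops (created by feature planting at codon
# boundaries or by substitution divergence): the first codon base not under
# the protection mask is set to "C", which can never complete a stop codon.
# Keeps every reference allele a clean open reading frame without touching
# planted/conserved bases.
fix_inframe_stops <- function(seq_chr, model, protected = NULL) {
  if (is.null(protected)) protected <- rep(FALSE, nchar(seq_chr))
  cds <- as.character(extractCDS(model, seq_chr))
  ncod <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  bad <- which(codons %in% STOPS & seq_len(ncod) < ncod)
  if (!length(bad)) return(seq_chr)
  # CDS position -> genomic position (simulator models are plus strand)
  gpos <- unlist(lapply(seq_along(model@cds), function(i)
    seq(start(model@cds)[i], end(model@cds)[i])))
  for (b in bad) {
    cand <- gpos[(3 * b - 2):(3 * b)]
    free <- cand[!protected[cand]]
    if (!length(free))
      stop("generation error: planted features force an in-frame stop codon")
    substring(seq_chr, free[1], free[1]) <- "C"
  }
  seq_chr
}

#' Simulate a homoeologue triplet with known divergence
#'
#' Builds an ancestral gene (flank - exons/introns - flank) whose spliced CDS
#' is a clean open reading frame (ATG ... stop), plants any requested enzyme
#' recognition sites, then derives the A, B and D homoeologues by independent
#' per-site substitution outside the conserved windows. All three members
#' share the exon/CDS structure. Substitutions that would create an in-frame
#' premature stop are repaired at the third codon base so every reference
#' allele remains functional.
#'
#' @param params a \code{\link{tripletSimParams}} object.
#' @return list with elements \code{triplet}
#'   (\linkS4class{HomoeologueTriplet}) and \code{truth} (data.frame of
#'   substituted sites: subgenome, pos, ref, alt).
#' @export
simulateTriplet <- function(params) {
  stopifnot(inherits(params, "TripletSimParams"))
  with_local_rng(params$seed, {
    exlen <- sample(seq(params$exon_len[1], params$exon_len[2]),
                    params$n_exons, replace = TRUE)
    exlen <- pmax(3L, (exlen %/% 3L) * 3L)
    inlen <- if (params$n_exons > 1)
      sample(seq(params$intron_len[1], params$intron_len[2]),
             params$n_exons - 1L, replace = TRUE) else integer()
    ncod <- sum(exlen) %/% 3L
    cds <- paste0("ATG", paste(random_codons(ncod - 2L), collapse = ""), "TGA")
    # distribute the CDS across exons, introns are GT...AG
    pieces <- character()
    exon_rng <- IRanges()
    pos <- params$flank_len
    off <- 0L
    for (i in seq_len(params$n_exons)) {
      pieces <- c(pieces, substring(cds, off + 1L, off + exlen[i]))
      exon_rng <- c(exon_rng, IRanges(pos + 1L, pos + exlen[i]))
      pos <- pos + exlen[i]
      off <- off + exlen[i]
      if (i < params$n_exons) {
        intr <- paste0("GT",
                       paste(sample(BASES, inlen[i] - 4L, replace = TRUE),
                             collapse = ""), "AG")
        pieces <- c(pieces, intr)
        pos <- pos + inlen[i]
      }
    }
    flank <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
    anc <- paste0(flank(params$flank_len), paste(pieces, collapse = ""),
                  flank(params$flank_len))
    # plant enzyme sites and full guide targets; planted features must agree
    # on any base they share
    feats <- c(
      lapply(params$planted_enzyme_sites, function(ps)
        list(at = ps$at, seq = toupper(ps$seq))),
      lapply(params$planted_guide_targets, function(pg)
        list(at = pg$at,
             seq = planted_target_seq(
               first_base = if (is.null(pg$first_base)) "A" else pg$first_base,
               enzyme = if (is.null(pg$enzyme)) "GAATTC" else pg$enzyme))))
    if (length(feats) > 1) {
      for (i in seq_len(length(feats) - 1)) for (j in (i + 1):length(feats)) {
        a <- feats[[i]]; b <- feats[[j]]
        lo <- max(a$at, b$at)
        hi <- min(a$at + nchar(a$seq), b$at + nchar(b$seq)) - 1L
        if (lo <= hi &&
            substring(a$seq, lo - a$at + 1L, hi - a$at + 1L) !=
            substring(b$seq, lo - b$at + 1L, hi - b$at + 1L))
          stop("generation error: planted features overlap with ",
               "incompatible bases")
      }
    }
    for (f in feats) {
      if (f$at < 1 || f$at + nchar(f$seq) - 1 > nchar(anc))
        stop("generation error: planted feature outside gene")
      substring(anc, f$at, f$at + nchar(f$seq) - 1L) <- f$seq
    }
    conserved <- rep(FALSE, nchar(anc))
    for (w in params$conserved_windows) {
      if (w[1] < 1 || w[2] > nchar(anc))
        stop("generation error: conserved window outside gene length")
      conserved[w[1]:w[2]] <- TRUE
    }
    for (f in feats)
      conserved[f$at:(f$at + nchar(f$seq) - 1L)] <- TRUE

    # planting at a codon boundary can complete a stop codon out of flanking
    # bases; repair the ancestor once so all members inherit the same fix
    anc_model <- GeneModel(geneId = "sim7AG1", chrom = "7A", strand = "+",
                           exons = exon_rng, cds = exon_rng,
                           transcriptIds = "sim7AG1.1", cdsComplete = TRUE)
    anc <- fix_inframe_stops(anc, anc_model, protected = conserved)

    L <- nchar(anc)
    models <- list(); seqs <- character(); truth <- list()
    for (sg in c("A", "B", "D")) {
      s <- anc
      hit <- which(runif(L) < params$divergence & !conserved)
      refb <- character(0); altb <- character(0)
      if (length(hit)) {
        refb <- substring(s, hit, hit)
        altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1),
                       character(1), USE.NAMES = FALSE)
        for (j in seq_along(hit)) substring(s, hit[j], hit[j]) <- altb[j]
      }
      if (params$inter_homoeologue_indels && sg != "A") {
        # a small 3' flank deletion; gene-body coordinates untouched
        del_at <- nchar(s) - params$flank_len +
          sample(seq_len(params$flank_len - 6L), 1)
        s <- paste0(substring(s, 1, del_at - 1),
                    substring(s, del_at + sample(1:3, 1)))
      }
      m <- GeneModel(geneId = paste0("sim7", sg, "G1"),
                     chrom = paste0("7", sg), strand = "+",
                     exons = exon_rng, cds = exon_rng,
                     transcriptIds = paste0("sim7", sg, "G1.1"),
                     cdsComplete = TRUE)
      s <- fix_inframe_stops(s, m, protected = conserved)
      models[[sg]] <- m
      seqs[sg] <- s
      if (length(hit))
        truth[[sg]] <- data.frame(subgenome = sg, pos = hit, ref = refb,
                                  alt = altb, stringsAsFactors = FALSE)
    }
    triplet <- HomoeologueTriplet(
      label = "simTriplet",
      models = models,
      seqs = DNAStringSet(seqs))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(subgenome = character(), pos = integer(),
                 ref = character(), alt = character())
    rownames(truth) <- NULL
    list(triplet = triplet, truth = truth)
  })
}

#' Parameters for the stamen/pistil counts simulator
#'
#' Defaults emulate a six-library booting-stage wheat experiment: three
#' stamen and three pistil replicates, negative-binomial counts with a
#' moderate biological dispersion, and a designated fraction of genes
#' differentially expressed at a fixed log2 fold change (alternating
#' stamen-up / pistil-up).
#'
#' @param n_genes number of genes.
#' @param n_reps_per_tissue replicates per tissue (default 3).
#' @param library_sizes vector (length 2*n_reps) of library sizes; a single
#'   number is recycled.
#' @param nb_dispersion NB dispersion (1/size); 0 gives Poisson counts.
#' @param de_fraction fraction of genes that are truly DE.
#' @param log2_fold_change absolute log2 fold change of the DE genes.
#' @param mean_log,sd_log log-normal parameters of baseline expression.
#' @param seed integer seed.
#' @return a \code{CountsSimParams} list.
#' @export
countsSimParams <- function(n_genes = 2000, n_reps_per_tissue = 3,
                            library_sizes = 1e6, nb_dispersion = 0.05,
                            de_fraction = 0.1, log2_fold_change = 2,
                            mean_log = log(50), sd_log = 1, seed = 1L) {
  stopifnot(n_genes > 0, n_reps_per_tissue > 0, all(library_sizes > 0),
            nb_dispersion >= 0, de_fraction >= 0, de_fraction <= 1)
  nlib <- 2L * n_reps_per_tissue
  if (length(library_sizes) == 1L) library_sizes <- rep(library_sizes, nlib)
  stopifnot(length(library_sizes) == nlib)
  structure(list(n_genes = as.integer(n_genes),
                 n_reps_per_tissue = as.integer(n_reps_per_tissue),
                 library_sizes = library_sizes,
                 nb_dispersion = nb_dispersion, de_fraction = de_fraction,
                 log2_fold_change = log2_fold_change,
                 mean_log = mean_log, sd_log = sd_log,
                 seed = as.integer(seed)),
            class = "CountsSimParams")
}

#' Simulate a stamen/pistil count table with truth DE labels
#'
#' @param params a \code{\link{countsSimParams}} object.
#' @return list with \code{counts} (matrix, genes x libraries; columns
#'   \code{stamen_1..n, pistil_1..n}) and \code{truth} (data.frame gene_id,
#'   is_de, log2fc with stamen as numerator).
#' @export
simulateCounts <- function(params) {
  stopifnot(inherits(params, "CountsSimParams"))
  with_local_rng(params$seed, {
    ng <- params$n_genes
    nr <- params$n_reps_per_tissue
    base <- rlnorm(ng, params$mean_log, params$sd_log)
    n_de <- floor(params$de_fraction * ng)
    lfc <- rep(0, ng)
    if (n_de > 0)
      lfc[seq_len(n_de)] <- params$log2_fold_change *
        rep_len(c(1, -1), n_de)
    # relative abundance per tissue, normalized to proportions
    ab_s <- base * 2^(lfc / 2)
    ab_p <- base * 2^(-lfc / 2)
    pr_s <- ab_s / sum(ab_s)
    pr_p <- ab_p / sum(ab_p)
    libs <- params$library_sizes
    draw <- function(mu) {
      if (params$nb_dispersion < 1e-12) rpois(ng, mu)
      else rnbinom(ng, mu = mu, size = 1 / params$nb_dispersion)
    }
    counts <- matrix(0L, ng, 2L * nr,
                     dimnames = list(sprintf("gene_%04d", seq_len(ng)),
                                     c(paste0("stamen_", seq_len(nr)),
                                       paste0("pistil_", seq_len(nr)))))
    for (r in seq_len(nr)) {
      counts[, r] <- draw(pr_s * libs[r])
      counts[, nr + r] <- draw(pr_p * libs[nr + r])
    }
    truth <- data.frame(gene_id = rownames(counts),
                        is_de = seq_len(ng) <= n_de,
                        log2fc = lfc, stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
}

#' Default indel size spectrum for Cas9 cut-site edits
#'
#' A simple small-indel-dominated spectrum (negative = deletion, positive =
#' insertion) typical of NHEJ repair; sizes and weights are a generator
#' choice, bounded by the largest events the genotyper must handle.
#'
#' @return named numeric vector: names are signed sizes, values are
#'   probabilities summing to 1.
#' @export
defaultIndelSpectrum <- function() {
  p <- c("-1" = 0.25, "-2" = 0.13, "-3" = 0.08, "-4" = 0.09, "-5" = 0.05,
         "-6" = 0.04, "-9" = 0.02, "-12" = 0.01, "1" = 0.22, "2" = 0.06,
         "3" = 0.03, "4" = 0.01, "6" = 0.01)
  p / sum(p)
}

#' Parameters for the edited-cohort simulator
#'
#' @param n_plants number of T0 plants.
#' @param per_allele_edit_prob probability that a given allele carries an
#'   edit at one of the guide cut sites.
#' @param indel_size_distribution named probability vector over signed
#'   nonzero indel sizes (see \code{\link{defaultIndelSpectrum}}).
#' @param max_deletion,max_insertion bounds on event size in bp; defaults
#'   span the largest events reported for this editing system (1,029 bp
#'   deletion, 118 bp insertion).
#' @param cut_offset_from_pam blunt-cut offset, bp 5' of the PAM (default 3).
#' @param seed integer seed.
#' @return an \code{EditSimParams} list.
#' @export
editSimParams <- function(n_plants = 20, per_allele_edit_prob = 0.5,
                          indel_size_distribution = defaultIndelSpectrum(),
                          max_deletion = 1029, max_insertion = 118,
                          cut_offset_from_pam = 3, seed = 1L) {
  sz <- as.integer(names(indel_size_distribution))
  stopifnot(n_plants > 0, per_allele_edit_prob >= 0,
            per_allele_edit_prob <= 1, all(sz != 0),
            all(indel_size_distribution >= 0),
            all(sz >= -max_deletion), all(sz <= max_insertion))
  structure(list(n_plants = as.integer(n_plants),
                 per_allele_edit_prob = per_allele_edit_prob,
                 indel_size_distribution = indel_size_distribution,
                 max_deletion = max_deletion, max_insertion = max_insertion,
                 cut_offset_from_pam = cut_offset_from_pam,
                 seed = as.integer(seed)),
            class = "EditSimParams")
}

# build the truth variant record for a single simulated cut-site indel; the
# record goes through the same left-alignment normalization and consequence
# rules as genotyper calls, so truth and pipeline representations are
# directly comparable (the pipeline must still recover the event by
# alignment)
truth_indel_variant <- function(refseq, cut_after, size) {
  if (size < 0) {
    pos <- cut_after + 1L
    if (pos - size - 1L > nchar(refseq))
      size <- -(nchar(refseq) - pos + 1L)
    data.frame(pos = pos, ref = substring(refseq, pos, pos - size - 1L),
               alt = "", length_change = size, stringsAsFactors = FALSE)
  } else {
    ins <- paste(sample(BASES, size, replace = TRUE), collapse = "")
    data.frame(pos = cut_after, ref = "", alt = ins, length_change = size,
               stringsAsFactors = FALSE)
  }
}

#' Simulate a cohort of Cas9-edited T0 plants
#'
#' For each plant and each of its six alleles (2 per homoeologue), an indel
#' is placed at the blunt cut site of a randomly chosen guide with
#' probability \code{per_allele_edit_prob}. Amplicons (here, the full member
#' gene sequences, which cover all guide sites) are emitted per allele with
#' ids \code{"plant|homoeologue|allele"}; the truth record carries each
#' allele's variant, consequence and functional flag plus the plant-level
#' fertility label under the six-allele rule.
#'
#' @param triplet a \linkS4class{HomoeologueTriplet} whose members are all
#'   hit by the guides.
#' @param guides guide table from \code{\link{designGuides}} /
#'   \code{\link{filterConserved}} (needs \code{cut_after_A/B/D} columns).
#' @param params an \code{\link{editSimParams}} object.
#' @return list with \code{amplicons} (named \code{DNAStringSet}),
#'   \code{truth_alleles} (data.frame: plant_id, homoeologue, allele_index,
#'   edited, pos, size, consequence, functional) and \code{truth_plants}
#'   (data.frame: plant_id, n_functional, fertility).
#' @export
simulateEditedPlants <- function(triplet, guides, params) {
  stopifnot(inherits(params, "EditSimParams"), nrow(guides) >= 1)
  sgs <- names(tripletModels(triplet))
  stopifnot(all(c("A", "B", "D") %in% sgs))
  need <- paste0("cut_after_", c("A", "B", "D"))
  stopifnot(all(need %in% names(guides)))
  with_local_rng(params$seed, {
    sizes <- as.integer(names(params$indel_size_distribution))
    pr <- params$indel_size_distribution
    amp <- character(); amp_ids <- character()
    rows <- list(); k <- 0L
    for (p in seq_len(params$n_plants)) {
      pid <- sprintf("plant_%03d", p)
      for (sg in c("A", "B", "D")) {
        refseq <- as.character(tripletSeqs(triplet)[[sg]])
        model <- tripletModels(triplet)[[sg]]
        for (al in 1:2) {
          edited <- runif(1) < params$per_allele_edit_prob
          if (edited) {
            g <- sample.int(nrow(guides), 1)
            cut_after <- guides[[paste0("cut_after_", sg)]][g]
            size <- sizes[sample.int(length(sizes), 1, prob = pr)]
            v <- truth_indel_variant(refseq, cut_after, size)
            v <- leftAlignVariants(v, refseq)
            seq_out <- applyVariants(refseq, v)
            cons <- predictConsequence(v, model, refseq)
            pos <- v$pos; size <- v$length_change
          } else {
            pos <- NA_integer_; size <- NA_integer_
            seq_out <- refseq
            cons <- list(consequence = "wild_type", functional = TRUE)
          }
          k <- k + 1L
          rows[[k]] <- data.frame(
            plant_id = pid, homoeologue = sg, allele_index = al,
            edited = edited, pos = pos, size = size,
            consequence = cons$consequence, functional = cons$functional,
            stringsAsFactors = FALSE)
          amp <- c(amp, seq_out)
          amp_ids <- c(amp_ids, paste(pid, sg, al, sep = "|"))
        }
      }
    }
    truth_alleles <- do.call(rbind, rows)
    truth_plants <- do.call(rbind, lapply(split(truth_alleles,
                                                truth_alleles$plant_id),
      function(d) data.frame(plant_id = d$plant_id[1],
                             n_functional = sum(d$functional),
                             fertility = if (sum(d$functional) == 0)
                               "sterile" else "fertile",
                             stringsAsFactors = FALSE)))
    truth_plants <- truth_plants[order(truth_plants$plant_id), ]
    rownames(truth_plants) <- NULL
    amps <- DNAStringSet(amp)
    names(amps) <- amp_ids
    list(amplicons = amps, truth_alleles = truth_alleles,
         truth_plants = truth_plants)
  })
}
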