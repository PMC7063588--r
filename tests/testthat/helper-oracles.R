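# Independent oracles and fixture builders used across the suite.

# Gotoh global affine-gap alignment score, O(nm) reference implementation.
# Gap of length L costs -(gap_open + L * gap_extend) with penalties given as
# negative numbers, matching alignScoring().
oracle_align_score <- function(a, b, scoring = alignScoring()) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  go <- -scoring$gap_open; ge <- -scoring$gap_extend
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (a aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + ge * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + ge * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) scoring$match else scoring$mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force Cas9 target scan: every 23-bp window on both strands with
# first base A/G, positions 22-23 "GG", no N.
oracle_find_targets <- function(s) {
  s <- toupper(s)
  scan <- function(x) {
    L <- nchar(x)
    hits <- integer()
    if (L >= 23) {
      for (i in seq_len(L - 22)) {
        w <- substring(x, i, i + 22)
        if (grepl("N", w, fixed = TRUE)) next
        if (substring(w, 1, 1) %in% c("A", "G") &&
            substring(w, 22, 23) == "GG")
          hits <- c(hits, i)
      }
    }
    hits
  }
  fwd <- scan(s)
  rc <- revcomp(s)
  rev <- scan(rc)
  out <- data.frame(protospacer = character(), strand = character(),
                    start = integer(), stringsAsFactors = FALSE)
  if (length(fwd))
    out <- rbind(out, data.frame(
      protospacer = substring(s, fwd, fwd + 19), strand = "+", start = fwd,
      stringsAsFactors = FALSE))
  if (length(rev)) {
    L <- nchar(s)
    out <- rbind(out, data.frame(
      protospacer = substring(rc, rev, rev + 19), strand = "-",
      start = L - rev - 21L, stringsAsFactors = FALSE))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random binary tree with positive branch lengths and its additive
# cophenetic distance matrix
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# a single-gene plus-strand model on a short sequence for consequence tests:
# exons/CDS given as IRanges
toy_model <- function(exons, cds = exons, chrom = "7A", strand = "+") {
  GeneModel(geneId = "toy1", chrom = chrom, strand = strand,
            exons = exons, cds = cds, transcriptIds = "toy1.1")
}

# standard planted-guide triplet used by guide and genotyping tests
planted_triplet <- function(seed = 3, divergence = 0.03) {
  simulateTriplet(tripletSimParams(
    seed = seed, divergence = divergence,
    planted_guide_targets = list(
      list(at = 131, first_base = "A", enzyme = "GAATTC"),
      list(at = 191, first_base = "G", enzyme = "GGATCC"))))
}

# designGuides on a two-target triplet always warns about the unfilled
# promoter slots (2 guides vs 4 slots); that warning is expected here
planted_guides <- function(sim) {
  suppressWarnings(designGuides(sim$triplet))
}
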