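# 23-mer planted-style window: A + 13 C + EcoRI site + CGG PAM
W_PROTO <- paste0("A", strrep("C", 13), "GAATTC")
W <- paste0(W_PROTO, "CGG")

# triplet with one exon/CDS model per member and caller-chosen sequences
craft_triplet <- function(seqs, exon_list) {
  models <- lapply(c(A = "A", B = "B", D = "D"), function(sg) {
    GeneModel(geneId = paste0("g", sg), chrom = paste0("7", sg),
              strand = "+", exons = exon_list[[sg]], cds = exon_list[[sg]],
              transcriptIds = paste0("g", sg, ".1"))
  })
  HomoeologueTriplet(label = "crafted", models = models,
                     seqs = Biostrings::DNAStringSet(seqs))
}

test_that("findTargets reports constructed plus and minus hits exactly", {
  # plus strand: W alone
  res <- findTargets(W)
  plus <- res[res$strand == "+", ]
  expect_identical(plus$protospacer, W_PROTO)
  expect_identical(plus$pam, "CGG")
  expect_identical(plus$start, 1L)
  expect_identical(plus$end, 23L)
  expect_identical(plus$cut_after, 17L)  # between protospacer pos 17 and 18
  # minus strand: G + 20A + GG seen only on the reverse complement
  w2 <- paste0("G", strrep("A", 20), "GG")
  s2 <- revcomp(w2)
  res2 <- findTargets(s2)
  expect_identical(nrow(res2), 1L)
  expect_identical(res2$strand, "-")
  expect_identical(res2$protospacer, substring(w2, 1, 20))
  expect_identical(res2$pam, "AGG")
  expect_identical(res2$start, 1L)
  expect_identical(res2$end, 23L)
  expect_identical(res2$cut_after, 6L)   # forward coordinate of the blunt cut
  # poly-T has no target on either strand
  expect_identical(nrow(findTargets(strrep("T", 50))), 0L)
  # too short for a window
  expect_identical(nrow(findTargets("ACGT")), 0L)
})

test_that("windows containing N are skipped", {
  wN <- paste0("A", strrep("C", 9), "N", strrep("C", 9), "CGG")
  expect_identical(nrow(findTargets(wN)), 0L)
})

test_that("first-base restriction filters candidates", {
  cfg_g <- guideConfig(first_base_alternatives = "G")
  expect_identical(nrow(findTargets(W, cfg_g)), 0L)
  expect_identical(nrow(findTargets(W, guideConfig())), 1L)
})

test_that("findTargets agrees with the brute-force oracle on random DNA", {
  set.seed(19)
  for (rep in 1:25) {
    s <- random_dna(1000)
    got <- findTargets(s)
    want <- oracle_find_targets(s)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$protospacer, want$protospacer)
    expect_identical(got$strand, want$strand)
    expect_identical(got$start, want$start)
    # structural invariants of every reported hit
    expect_true(all(got$end == got$start + 22L))
    expect_true(all(substring(got$pam, 2, 3) == "GG"))
    plus <- got$strand == "+"
    expect_true(all(got$cut_after[plus] == got$start[plus] + 16L))
    expect_true(all(got$cut_after[!plus] == got$start[!plus] + 5L))
  }
})

test_that("strand mirror: targets of revcomp(s) are mirrored targets of s", {
  set.seed(29)
  for (rep in 1:10) {
    s <- random_dna(400)
    L <- nchar(s)
    a <- findTargets(s)
    b <- findTargets(revcomp(s))
    expect_identical(nrow(a), nrow(b))
    mirrored <- data.frame(protospacer = b$protospacer,
                           strand = ifelse(b$strand == "+", "-", "+"),
                           start = L - b$end + 1L,
                           stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_identical(a$protospacer,  mirrored$protospacer)
    expect_identical(a$strand, mirrored$strand)
    expect_identical(a$start, mirrored$start)
  }
})

test_that("conservation requires an exact unique protospacer+NGG everywhere", {
  set.seed(37)
  mk <- function(flank5, flank3, core = W) paste0(flank5, core, flank3)
  f5 <- random_dna(60); f3 <- random_dna(40)
  seqs <- c(A = mk(f5, f3),
            B = mk(random_dna(60), random_dna(40),
                   core = paste0(W_PROTO, "AGG")),   # PAM N is free
            D = mk(random_dna(60), random_dna(40)))
  ex <- IRanges(61, 83)
  tri <- craft_triplet(seqs, list(A = ex, B = ex, D = ex))
  cands <- data.frame(
    protospacer = c(W_PROTO,
                    sub("^AC", "AG", W_PROTO)),  # 1-bp mismatch: not conserved
    pam = "CGG", strand = "+", start = 61L, end = 83L, cut_after = 77L,
    stringsAsFactors = FALSE)
  kept <- filterConserved(cands, tri)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$protospacer, W_PROTO)
  expect_identical(kept$start_A, 61L)
  expect_identical(kept$strand_B, "+")
  expect_identical(kept$cut_after_A, 77L)
  expect_true(kept$exon_overlap_A && kept$exon_overlap_B && kept$exon_overlap_D)
  # spliced distance of the cut from the CDS start (CDS begins at 61)
  expect_identical(kept$cds_dist_A, 16L)
  # a duplicated target in one homoeologue is non-unique: dropped, logged
  seqs_dup <- seqs
  seqs_dup["D"] <- paste0(seqs_dup["D"], random_dna(10), W)
  tri_dup <- craft_triplet(seqs_dup, list(A = ex, B = ex, D = ex))
  expect_message(kept_dup <- filterConserved(cands[1, ], tri_dup),
                 "non-unique")
  expect_identical(nrow(kept_dup), 0L)
})

test_that("conservation finds minus-strand occurrences in forward coords", {
  set.seed(43)
  rcW <- revcomp(W)
  seqs <- vapply(1:3, function(i) paste0(random_dna(50), rcW, random_dna(30)),
                 character(1))
  names(seqs) <- c("A", "B", "D")
  ex <- IRanges(51, 73)
  tri <- craft_triplet(seqs, list(A = ex, B = ex, D = ex))
  cands <- data.frame(protospacer = W_PROTO, pam = "CGG",
                      stringsAsFactors = FALSE)
  kept <- filterConserved(cands, tri)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$strand_A, "-")
  expect_identical(kept$start_A, 51L)
  expect_identical(kept$end_A, 73L)
  expect_identical(kept$cut_after_A, 56L)
  expect_true(kept$exon_overlap_A)
  expect_identical(kept$cds_dist_A, 5L)
})

test_that("exon overlap needs one protospacer base in all three members", {
  set.seed(47)
  f5 <- random_dna(60)
  seqs <- c(A = paste0(f5, W, random_dna(40)),
            B = paste0(random_dna(60), W, random_dna(40)),
            D = paste0(random_dna(60), W, random_dna(40)))
  cands <- data.frame(protospacer = W_PROTO, pam = "CGG",
                      stringsAsFactors = FALSE)
  # protospacer spans 61..80: an exon starting at its last base overlaps
  tri1 <- craft_triplet(seqs, list(A = IRanges(61, 83), B = IRanges(80, 90),
                                   D = IRanges(61, 83)))
  kept1 <- filterExonic(filterConserved(cands, tri1))
  expect_identical(nrow(kept1), 1L)
  # an exon beginning downstream of the protospacer does not
  tri2 <- craft_triplet(seqs, list(A = IRanges(61, 83), B = IRanges(84, 92),
                                   D = IRanges(61, 83)))
  cons2 <- filterConserved(cands, tri2)
  expect_false(cons2$exon_overlap_B)
  expect_identical(nrow(filterExonic(cons2)), 0L)
})

test_that("restriction screenability demands a cut-spanning site", {
  cfg <- guideConfig()
  mk_cand <- function(window) data.frame(
    protospacer = substring(window, 1, 20), pam = substring(window, 21, 23),
    stringsAsFactors = FALSE)
  # EcoRI at protospacer positions 15-20 spans the 17|18 cut: retained
  w_mid <- paste0(strrep("A", 14), "GAATTC", "AGG")
  out <- filterRestrictionScreenable(mk_cand(w_mid), cfg)
  expect_identical(nrow(out), 1L)
  expect_identical(out$screenable_enzymes, "EcoRI")
  # the same site at positions 2-7 is far from the cut: removed
  w_early <- paste0("C", "GAATTC", strrep("A", 13), "AGG")
  expect_identical(
    nrow(filterRestrictionScreenable(mk_cand(w_early), cfg)), 0L)
  # a site straddling from position 17 into the PAM still spans the cut
  w_straddle <- paste0(strrep("C", 16), "GAATTC", "G")
  out3 <- filterRestrictionScreenable(mk_cand(w_straddle), cfg)
  expect_identical(nrow(out3), 1L)
  # boundary: site ending exactly at position 18 spans; starting at 18 not
  w_end18 <- paste0(strrep("C", 12), "GAATTC", strrep("A", 2), "AGG")
  expect_identical(nrow(filterRestrictionScreenable(mk_cand(w_end18), cfg)), 1L)
  w_start18 <- paste0(strrep("C", 17), "GAATTC")
  expect_identical(
    nrow(filterRestrictionScreenable(mk_cand(w_start18), cfg)), 0L)
  # a non-palindromic enzyme matches through its reverse complement
  bsaI <- data.frame(name = "BsaI", site = "GGTCTC", stringsAsFactors = FALSE)
  cfg_bsa <- guideConfig(enzymes = bsaI)
  w_rc <- paste0(strrep("A", 14), revcomp("GGTCTC"), "AGG")
  out_rc <- filterRestrictionScreenable(mk_cand(w_rc), cfg_bsa)
  expect_identical(out_rc$screenable_enzymes, "BsaI")
  # several qualifying enzymes are comma-joined
  multi <- data.frame(name = c("EcoRI", "Fake"), site = c("GAATTC", "AATTCA"),
                      stringsAsFactors = FALSE)
  w_multi <- paste0(strrep("A", 14), "GAATTCA", "GG")
  out_m <- filterRestrictionScreenable(mk_cand(w_multi),
                                       guideConfig(enzymes = multi))
  expect_identical(out_m$screenable_enzymes, "EcoRI,Fake")
})

test_that("ranking sorts by worst-case CDS distance with defined tie-breaks", {
  cands <- data.frame(
    protospacer = c(paste0("A", strrep("C", 19)),
                    paste0("G", strrep("C", 19)),
                    paste0("A", strrep("G", 19)),
                    paste0("G", strrep("A", 19))),
    pam = "CGG",
    cds_dist_A = c(50L, 10L, 300L, 10L),
    cds_dist_B = c(60L, 12L, 280L, 12L),
    cds_dist_D = c(55L, 11L, 310L, 12L),
    stringsAsFactors = FALSE)
  ranked <- rankAndAssign(cands, guideConfig())
  # worst-case distances: 60, 12, 310, 12; tie at 12 broken by protospacer
  expect_identical(ranked$rank_score, c(12L, 12L, 60L, 310L))
  expect_identical(substring(ranked$protospacer[1], 1, 1), "G")
  # slots OsU3, OsU6, TaU3, TaU6 prefer A/G/A/G first bases
  expect_identical(ranked$promoter_slot[ranked$protospacer ==
                                          cands$protospacer[1]], "OsU3")
  # ranks: cand4 (G, 12) < cand2 (G, 12) < cand1 (A, 60) < cand3 (A, 310);
  # greedy assignment gives OsU3 the best A-initial, OsU6 the best G-initial
  expect_identical(ranked$promoter_slot[ranked$protospacer ==
                                          cands$protospacer[1]], "OsU3")
  expect_identical(ranked$promoter_slot[ranked$protospacer ==
                                          cands$protospacer[4]], "OsU6")
  expect_identical(ranked$promoter_slot[ranked$protospacer ==
                                          cands$protospacer[2]], "TaU6")
  expect_setequal(ranked$promoter_slot, c("OsU3", "OsU6", "TaU3", "TaU6"))
  # shortfall warns about promoter duplication
  expect_warning(short <- rankAndAssign(cands[1:2, ], guideConfig()),
                 "duplicated")
  expect_identical(nrow(short), 2L)
  # nothing passing warns too
  expect_warning(none <- rankAndAssign(cands[0, ], guideConfig()),
                 "no guide candidates")
  expect_identical(nrow(none), 0L)
})

test_that("end-to-end design recovers planted targets and self-validates", {
  sim <- planted_triplet(seed = 3)
  guides <- planted_guides(sim)
  expect_identical(nrow(guides), 2L)
  expect_setequal(substring(guides$protospacer, 1, 1), c("A", "G"))
  expect_true(any(grepl("EcoRI", guides$screenable_enzymes)))
  expect_true(any(grepl("BamHI", guides$screenable_enzymes)))
  expect_true(validateGuides(guides, sim$triplet))
  expect_false(any(is.na(guides$promoter_slot)))
  # A-initial guide on a U3 promoter, G-initial on U6
  a_slot <- guides$promoter_slot[substring(guides$protospacer, 1, 1) == "A"]
  g_slot <- guides$promoter_slot[substring(guides$protospacer, 1, 1) == "G"]
  expect_true(grepl("U3", a_slot))
  expect_true(grepl("U6", g_slot))
})

test_that("planted targets survive design across seeds and high divergence", {
  for (seed in c(1, 2, 9)) {
    sim <- planted_triplet(seed = seed, divergence = 0.10)
    guides <- planted_guides(sim)
    # both planted protospacers survive; chance-conserved extras may join
    seqA <- as.character(tripletSeqs(sim$triplet)[["A"]])
    planted <- c(substring(seqA, 131, 150), substring(seqA, 191, 210))
    expect_true(all(planted %in% guides$protospacer))
    expect_lte(nrow(guides), 4L)
    expect_true(validateGuides(guides, sim$triplet))
  }
})

test_that("guide report writes a provenance header, TSV and FASTA", {
  sim <- planted_triplet(seed = 3)
  guides <- planted_guides(sim)
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fasta")
  writeGuideReport(guides, tsv, fa, header = c("# tool: test", "# seed: 3"))
  lines <- readLines(tsv)
  expect_identical(lines[1], "# tool: test")
  back <- read.delim(tsv, comment.char = "#", stringsAsFactors = FALSE)
  expect_identical(back$protospacer, guides$protospacer)
  pros <- readFastaRecords(fa)
  expect_identical(unname(as.character(pros)), guides$protospacer)
  expect_true(all(grepl("^guide_\\d2|^guide_", names(pros))))
})
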