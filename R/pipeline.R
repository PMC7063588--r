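# End-to-end orchestration: candidate triage -> family census -> guide
# design -> edited-cohort genotyping, with provenance headers on every
# output. A thin command-line wrapper over these functions ships in
# inst/scripts/wheatgms.R.

#' Provenance header lines for an output file
#'
#' \code{#}-prefixed lines recording the package version, the seed and a
#' digest of the configuration, so re-runs are diffable and attributable.
#'
#' @param seed integer seed in effect.
#' @param config the configuration list used (hashed, not dumped).
#' @return character vector of header lines.
#' @export
provenanceHeader <- function(seed, config = list()) {
  ver <- as.character(utils::packageVersion("wheatGMS"))
  hash <- sprintf("%08x",
                  sum(utf8ToInt(paste(deparse(config), collapse = ""))) %%
                    .Machine$integer.max)
  c(sprintf("# wheatGMS %s", ver),
    sprintf("# seed: %d", as.integer(seed)),
    sprintf("# config: %s", hash))
}

#' Write a table as TSV with a provenance header
#'
#' @param x data.frame.
#' @param path output path.
#' @param seed,config passed to \code{\link{provenanceHeader}}.
#' @return invisibly, \code{path}.
#' @export
writeProvenancedTSV <- function(x, path, seed, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(seed, config), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV (gene_id + library columns)
#'
#' Lines starting with \code{#} are skipped.
#'
#' @param path TSV path with a \code{gene_id} column.
#' @return numeric matrix with gene rownames.
#' @export
readCountsTSV <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(d))
    stop("schema error: counts table lacks a gene_id column")
  m <- as.matrix(d[setdiff(names(d), "gene_id")])
  rownames(m) <- d$gene_id
  storage.mode(m) <- "numeric"
  m
}

#' Run the whole workflow on simulated fixtures
#'
#' Generates a homoeologue triplet and a stamen/pistil count table, runs the
#' DE triage, a family census over a toy domain annotation built from the
#' triplet, guide design, an edited T0 cohort, and the genotyper, writing
#' every result under \code{outdir} with provenance headers. All randomness
#' derives from \code{seed}; re-runs are byte-identical.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer master seed.
#' @param n_plants size of the simulated edited cohort.
#' @param counts_params optional \code{\link{countsSimParams}} override.
#' @param triplet_params optional \code{\link{tripletSimParams}} override.
#' @return invisibly, a list with the computed objects and output paths.
#' @export
runPipeline <- function(outdir, seed = 1, n_plants = 20,
                        counts_params = NULL, triplet_params = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  cfg <- list(seed = seed, n_plants = n_plants)
  p <- function(f) file.path(outdir, f)

  # --- synthetic inputs -------------------------------------------------
  if (is.null(triplet_params))
    triplet_params <- tripletSimParams(
      divergence = 0.03,
      planted_guide_targets = list(
        list(at = 131, first_base = "A", enzyme = "GAATTC"),
        list(at = 191, first_base = "G", enzyme = "GGATCC")),
      seed = seed)
  sim_trip <- simulateTriplet(triplet_params)
  triplet <- sim_trip$triplet
  writeFastaRecords(tripletSeqs(triplet), p("triplet.fasta"))
  writeGFF3(tripletModels(triplet), p("triplet.gff3"))

  if (is.null(counts_params))
    counts_params <- countsSimParams(n_genes = 500, seed = seed + 1L)
  sim_cnt <- simulateCounts(counts_params)

  # --- DE triage --------------------------------------------------------
  tri_cfg <- triageConfig()
  de <- triageCandidates(sim_cnt$counts, tri_cfg)
  writeProvenancedTSV(de, p("de_results.tsv"), seed, cfg)
  de_sum <- deSummary(de)

  # --- family census on a toy annotation built from the triplet --------
  ann <- data.frame(
    transcript_id = unlist(lapply(tripletModels(triplet), transcriptIds)),
    gene_id = vapply(tripletModels(triplet), geneId, ""),
    chrom = vapply(tripletModels(triplet), function(m) m@chrom, ""),
    pfam_id = "PFSIM01", stringsAsFactors = FALSE)
  ann$subgenome <- subgenomeOf(ann$chrom)
  census <- enumerateFamily(ann, "PFSIM01")
  writeProvenancedTSV(
    data.frame(pfam_id = census$pfam_id, t(census$counts),
               total = census$total),
    p("family_census.tsv"), seed, cfg)
  tree <- familyTree(tripletSeqs(triplet))
  writeNewick(tree, p("family_tree.nwk"))

  # --- guide design -----------------------------------------------------
  g_cfg <- guideConfig()
  guides <- designGuides(triplet, g_cfg)
  writeGuideReport(guides, p("guides.tsv"), p("guides.fasta"),
                   header = provenanceHeader(seed, cfg))

  # --- edited cohort + genotyping --------------------------------------
  if (nrow(guides)) {
    e_par <- editSimParams(n_plants = n_plants, seed = seed + 2L)
    cohort <- simulateEditedPlants(triplet, guides, e_par)
    writeFastaRecords(cohort$amplicons, p("amplicons.fasta"))
    writeProvenancedTSV(cohort$truth_plants, p("truth_plants.tsv"), seed, cfg)
    geno <- genotypePlants(cohort$amplicons, triplet)
    writeProvenancedTSV(geno$alleles, p("genotype_alleles.tsv"), seed, cfg)
    writeProvenancedTSV(geno$plants, p("genotype_plants.tsv"), seed, cfg)
  } else {
    cohort <- NULL; geno <- NULL
  }

  invisible(list(triplet = triplet, counts = sim_cnt, de = de,
                 de_summary = de_sum, census = census, tree = tree,
                 guides = guides, cohort = cohort, genotype = geno,
                 outdir = outdir))
}
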