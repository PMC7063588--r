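# Candidate-selection logic for the stamen/pistil differential-expression
# screen: low-count floor, exact conditional test on replicate-summed counts,
# BH FDR, homoeologue-set significance codes and candidate ranking.

#' Triage configuration
#'
#' @param min_total_reads genes with fewer total reads than this across all
#'   six libraries are removed (default 10; "less than" excludes the
#'   boundary, so a total of exactly 10 is retained).
#' @param fdr_cutoff FDR significance cutoff (default 0.05).
#' @param n_stamen_libs,n_pistil_libs replicates per tissue (default 3).
#' @param set_direction which direction counts toward the homoeologue-set
#'   code: \code{"stamen"} (default; candidates are stamen-prioritized) or
#'   \code{"any"}.
#' @return a \code{TriageConfig} list.
#' @export
triageConfig <- function(min_total_reads = 10, fdr_cutoff = 0.05,
                         n_stamen_libs = 3, n_pistil_libs = 3,
                         set_direction = c("stamen", "any")) {
  stopifnot(min_total_reads >= 0, fdr_cutoff > 0, fdr_cutoff < 1,
            n_stamen_libs >= 1, n_pistil_libs >= 1)
  structure(list(min_total_reads = min_total_reads,
                 fdr_cutoff = fdr_cutoff,
                 n_stamen_libs = as.integer(n_stamen_libs),
                 n_pistil_libs = as.integer(n_pistil_libs),
                 set_direction = match.arg(set_direction)),
            class = "TriageConfig")
}

split_tissues <- function(counts, config) {
  nlib <- config$n_stamen_libs + config$n_pistil_libs
  if (ncol(counts) != nlib)
    stop("schema error: expected ", nlib, " library columns, got ",
         ncol(counts))
  list(stamen = counts[, seq_len(config$n_stamen_libs), drop = FALSE],
       pistil = counts[, config$n_stamen_libs + seq_len(config$n_pistil_libs),
                       drop = FALSE])
}

#' Remove genes below the total-read floor
#'
#' Genes whose total mapped reads across all libraries fall below
#' \code{min_total_reads} are removed (strictly fewer: a total equal to the
#' floor is retained). The number removed is reported via \code{message()}.
#'
#' @param counts numeric matrix, genes x libraries (rownames = gene ids).
#' @param config a \code{\link{triageConfig}}.
#' @return the filtered count matrix.
#' @export
filterLowCounts <- function(counts, config = triageConfig()) {
  split_tissues(counts, config)  # schema check
  keep <- rowSums(counts) >= config$min_total_reads
  message(sum(!keep), " gene(s) removed by the low-count floor (< ",
          config$min_total_reads, " total reads)")
  counts[keep, , drop = FALSE]
}

#' Exact conditional test for stamen vs pistil expression
#'
#' Replicates are summed within tissue and each gene's pooled count
#' \eqn{n = x_s + x_p} is tested against the null that reads fall into the
#' stamen pool with probability \eqn{N_s / (N_s + N_p)} (the stamen share of
#' the total sequencing depth): a two-sided exact binomial test,
#' \eqn{p = \min(1,\; 2\min(P(X \le x_s), P(X \ge x_s)))}. The log2 fold
#' change is computed from depth-normalized per-tissue mean CPM with a
#' pseudo-count of 0.5. This is a deliberately simple stand-in for a
#' negative-binomial GLM: it is exact under Poisson sampling and
#' anticonservative under biological overdispersion, so a warning is emitted
#' when the within-tissue variance exceeds 3x the mean for a substantial
#' share of genes.
#'
#' @param counts filtered count matrix (genes x libraries).
#' @param config a \code{\link{triageConfig}}.
#' @return data.frame: gene_id, mean_stamen, mean_pistil (mean CPM),
#'   log2_fold_change (stamen over pistil), p_value; fdr and direction are
#'   filled by \code{\link{triageCandidates}} / \code{\link{adjustBH}}.
#' @export
testDifferential <- function(counts, config = triageConfig()) {
  ts <- split_tissues(counts, config)
  lib_s <- colSums(ts$stamen); lib_p <- colSums(ts$pistil)
  Ns <- sum(lib_s); Np <- sum(lib_p)
  if (Ns == 0 || Np == 0)
    stop("config error: zero total library size in one tissue")
  overdisp <- function(m) {
    mu <- rowMeans(m); v <- apply(m, 1, var)
    mean(v > 3 * mu & mu > 0, na.rm = TRUE)
  }
  if (ncol(ts$stamen) > 1 &&
      (overdisp(ts$stamen) > 0.1 || overdisp(ts$pistil) > 0.1))
    warning("within-tissue variance exceeds 3x the mean for many genes; ",
            "the exact conditional test assumes Poisson replicates and ",
            "will be anticonservative")
  xs <- rowSums(ts$stamen); xp <- rowSums(ts$pistil)
  n <- xs + xp
  pr <- Ns / (Ns + Np)
  lo <- pbinom(xs, n, pr)
  hi <- pbinom(xs - 1, n, pr, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lo, hi))
  p[n == 0] <- 1
  cpm_s <- rowMeans(sweep(ts$stamen, 2, lib_s, "/")) * 1e6
  cpm_p <- rowMeans(sweep(ts$pistil, 2, lib_p, "/")) * 1e6
  lfc <- log2((cpm_s + 0.5) / (cpm_p + 0.5))
  data.frame(gene_id = rownames(counts),
             mean_stamen = cpm_s, mean_pistil = cpm_p,
             log2_fold_change = lfc, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' clipped at 1, returned in the original order (delegates to
#' \code{stats::p.adjust(method = "BH")}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return the adjusted values (same length/order).
#' @export
adjustBH <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Run the full DE triage on a count table
#'
#' Low-count filter, exact test, BH adjustment and direction call in one
#' step. Direction is \code{"ns"} unless \code{fdr <= fdr_cutoff}, in which
#' case it follows the sign of the log2 fold change (stamen as numerator).
#'
#' @param counts raw count matrix (genes x libraries).
#' @param config a \code{\link{triageConfig}}.
#' @return DE results data.frame with columns gene_id, mean_stamen,
#'   mean_pistil, log2_fold_change, p_value, fdr, direction.
#' @export
triageCandidates <- function(counts, config = triageConfig()) {
  res <- testDifferential(filterLowCounts(counts, config), config)
  res$fdr <- adjustBH(res$p_value)
  res$direction <- ifelse(res$fdr > config$fdr_cutoff | res$log2_fold_change == 0,
                          "ns",
                          ifelse(res$log2_fold_change > 0, "stamen", "pistil"))
  res
}

#' Summarize DE bookkeeping with a consistency check
#'
#' Counts significant genes overall and by direction and enforces
#' \code{total = stamen_higher + pistil_higher} on any input (a gene is
#' significant only with a direction, so the identity must hold; violation
#' is an error, not a warning).
#'
#' @param results DE results with \code{direction} column (from
#'   \code{\link{triageCandidates}} or an external DE table recoded to the
#'   same schema).
#' @return list: total_de, n_stamen_higher, n_pistil_higher.
#' @export
deSummary <- function(results) {
  up <- sum(results$direction == "stamen")
  down <- sum(results$direction == "pistil")
  total <- sum(results$direction != "ns")
  if (total != up + down)
    stop("bookkeeping error: total DE (", total, ") != stamen-higher (", up,
         ") + pistil-higher (", down, ")")
  list(total_de = total, n_stamen_higher = up, n_pistil_higher = down)
}

#' Homoeologue-set significance codes
#'
#' For each homoeologue set, builds the code string over \code{"ABDU"} from
#' the members that are significant (fdr at or below the cutoff) in the
#' configured direction; letters are sorted A < B < D < U without repeats.
#' Set members absent from the DE results contribute nothing.
#'
#' @param results DE results (from \code{\link{triageCandidates}} or an
#'   external table with gene_id, fdr, direction).
#' @param set_table data.frame: set_id, gene_id, subgenome.
#' @param config a \code{\link{triageConfig}}.
#' @return data.frame: set_id, code, n_members, mean_sig_log2fc (mean
#'   log2FC over the significant members, NA when none).
#' @export
annotateHomoeologueSets <- function(results, set_table,
                                    config = triageConfig()) {
  stopifnot(all(c("set_id", "gene_id", "subgenome") %in% names(set_table)))
  idx <- match(set_table$gene_id, results$gene_id)
  fdr <- results$fdr[idx]
  dirn <- results$direction[idx]
  lfc <- results$log2_fold_change[idx]
  sig <- !is.na(fdr) & fdr <= config$fdr_cutoff &
    (if (config$set_direction == "stamen") dirn == "stamen" else dirn != "ns")
  out <- lapply(split(seq_len(nrow(set_table)), set_table$set_id), function(i) {
    s <- sig[i]
    code <- paste(sort(unique(set_table$subgenome[i][s])), collapse = "")
    data.frame(set_id = set_table$set_id[i][1], code = code,
               n_members = length(i),
               mean_sig_log2fc = if (any(s)) mean(lfc[i][s]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank candidate homoeologue sets
#'
#' Sorted by completeness of the significance code (three subgenomes before
#' two before one), then mean stamen log2 fold change of the significant
#' members (descending), then set_id (lexicographic tie-break). An optional
#' domain allow-list restricts output to sets annotated with one of the
#' given Pfam ids.
#'
#' @param labels output of \code{\link{annotateHomoeologueSets}}.
#' @param family_annotations optional data.frame (set_id, pfam_id).
#' @param allow_domains optional character vector of Pfam ids to keep.
#' @return the ranked (and possibly restricted) label table.
#' @export
rankCandidates <- function(labels, family_annotations = NULL,
                           allow_domains = NULL) {
  if (!is.null(allow_domains)) {
    stopifnot(!is.null(family_annotations))
    keep_ids <- unique(family_annotations$set_id[
      family_annotations$pfam_id %in% allow_domains])
    labels <- labels[labels$set_id %in% keep_ids, , drop = FALSE]
  }
  completeness <- nchar(labels$code)
  lfc <- ifelse(is.na(labels$mean_sig_log2fc), -Inf, labels$mean_sig_log2fc)
  ord <- order(-completeness, -lfc, labels$set_id)
  out <- labels[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' T0 sterility percentage as reported
#'
#' Percentage of sterile primary transformants, rounded to the reporting
#' precision (whole percent by default, matching how such screens are
#' reported: 9 of 64 plants is 14\%, 7 of 101 is 7\%).
#'
#' @param n_sterile number of sterile T0 plants.
#' @param n_total total T0 plants.
#' @param digits rounding digits for the percentage (default 0).
#' @return the percentage (numeric).
#' @export
sterilityRate <- function(n_sterile, n_total, digits = 0) {
  stopifnot(n_total > 0, n_sterile >= 0, n_sterile <= n_total)
  round(100 * n_sterile / n_total, digits)
}
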