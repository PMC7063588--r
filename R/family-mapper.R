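# Subgenome-resolved gene-family census by Pfam domain and a distance-based
# phylogeny of family members (global-alignment identity -> 1 - identity ->
# neighbor joining -> Newick).

#' Read a transcript-level domain annotation table
#'
#' Tab-delimited with header columns transcript_id, gene_id, chrom,
#' subgenome, pfam_id (subgenome may be omitted; it is then derived from the
#' chromosome token). A transcript must map to exactly one gene.
#'
#' @param path TSV path.
#' @return the annotation data.frame.
#' @export
readDomainAnnotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "chrom", "pfam_id")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("schema error: annotation lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!"subgenome" %in% names(ann))
    ann$subgenome <- subgenomeOf(ann$chrom)
  multi <- tapply(ann$gene_id, ann$transcript_id,
                  function(g) length(unique(g)))
  if (any(multi > 1))
    stop("annotation error: transcript mapped to more than one gene: ",
         paste(names(multi)[multi > 1][1:min(3, sum(multi > 1))],
               collapse = ", "))
  ann
}

#' Subgenome census of a Pfam-defined gene family
#'
#' Counts the loci carrying a given Pfam domain per subgenome. Splice
#' variants collapse to one locus per gene id, so a gene with several
#' annotated transcripts is counted once. An absent domain yields a
#' zero-count census (logged), not an error.
#'
#' @param annotation data.frame from \code{\link{readDomainAnnotation}} (or
#'   equivalent).
#' @param pfam_id Pfam domain id (e.g. \code{"PF14288"}).
#' @return list of class \code{FamilyCensus}: pfam_id, counts (named vector
#'   A/B/D/U), total, member_gene_ids.
#' @export
enumerateFamily <- function(annotation, pfam_id) {
  rows <- annotation[annotation$pfam_id == pfam_id, , drop = FALSE]
  if (!nrow(rows))
    message("no loci found for domain ", pfam_id)
  loci <- rows[!duplicated(rows$gene_id), , drop = FALSE]
  counts <- vapply(c("A", "B", "D", "U"),
                   function(sg) sum(loci$subgenome == sg), integer(1))
  structure(list(pfam_id = pfam_id, counts = counts,
                 total = sum(counts),
                 member_gene_ids = sort(unique(loci$gene_id))),
            class = "FamilyCensus")
}

#' @export
print.FamilyCensus <- function(x, ...) {
  cat(sprintf("FamilyCensus %s: A=%d B=%d D=%d U=%d (total %d)\n",
              x$pfam_id, x$counts["A"], x$counts["B"], x$counts["D"],
              x$counts["U"], x$total))
  invisible(x)
}

#' Alignment scoring scheme
#'
#' Defaults: match +1, mismatch -1, gap open -5, gap extension -1 per base
#' (a gap of length L costs 5 + L).
#'
#' @param match,mismatch,gap_open,gap_extend scoring parameters; penalties
#'   are given as negative numbers.
#' @return a scoring list.
#' @export
alignScoring <- function(match = 1, mismatch = -1, gap_open = -5,
                         gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

pairwise_aln <- function(a, b, scoring) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    pattern = as.character(a), subject = as.character(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
}

#' Global-alignment identity between two sequences
#'
#' Fraction of identical columns in the optimal global affine-gap alignment
#' (matches divided by total alignment columns, gaps included).
#'
#' @param a,b sequences (character or XString).
#' @param scoring an \code{\link{alignScoring}} list.
#' @return identity in [0, 1].
#' @export
pairwiseIdentity <- function(a, b, scoring = alignScoring()) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("pairwiseIdentity needs non-empty sequences")
  aln <- pairwise_aln(a, b, scoring)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Identity-based distance matrix for a set of sequences
#'
#' Distance = 1 - global-alignment identity, computed for every pair.
#'
#' @param seqs named \code{DNAStringSet} or character vector.
#' @param scoring an \code{\link{alignScoring}} list.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
identityDistanceMatrix <- function(seqs, scoring = alignScoring()) {
  s <- as.character(seqs)
  names(s) <- names(seqs)  # as.character() drops names from character input
  n <- length(s)
  stopifnot(n >= 2, !is.null(names(s)))
  d <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - pairwiseIdentity(s[i], s[j], scoring)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \code{ape::nj}) with input validation:
#' the matrix must be symmetric with a zero diagonal. Negative branch
#' lengths are clamped to zero with a warning. Output is deterministic given
#' the input label order.
#'
#' @param d symmetric distance matrix with labels.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 labels")
  if (is.null(rownames(d))) stop("distance matrix must carry labels")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("validation error: distance matrix is not symmetric")
  if (any(diag(d) != 0))
    stop("validation error: distance matrix diagonal must be zero")
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length <- pmax(tr$edge.length, 0)
  }
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree an \code{ape::phylo} object.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Family phylogeny from member sequences
#'
#' Convenience wrapper: identity distances then neighbor joining.
#'
#' @param seqs named \code{DNAStringSet} of (>= 3) family member sequences.
#' @param scoring an \code{\link{alignScoring}} list.
#' @return an \code{ape::phylo} tree.
#' @export
familyTree <- function(seqs, scoring = alignScoring()) {
  njTree(identityDistanceMatrix(seqs, scoring))
}
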