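#' @import methods
#' @importFrom IRanges IRanges start end width reduce
#' @importFrom S4Vectors isSorted
NULL

#' GeneModel: one locus on one wheat subgenome
#'
#' Gene structure for a single locus: exon and CDS intervals of the
#' representative (first) transcript in genomic coordinates, strand,
#' chromosome, subgenome assignment and the full set of transcript ids.
#' Intervals are 1-based closed \linkS4class{IRanges}, sorted,
#' non-overlapping; every CDS interval must lie within the exon union.
#'
#' @slot geneId single gene identifier.
#' @slot chrom chromosome token (e.g. \code{"7A"}, \code{"Un"}).
#' @slot subgenome one of \code{"A"}, \code{"B"}, \code{"D"}, \code{"U"}
#'   (unanchored).
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons exon intervals (genomic, ascending).
#' @slot cds CDS intervals (genomic, ascending); may be empty.
#' @slot transcriptIds ids of all transcripts at the locus; the first is the
#'   representative whose structure is stored.
#' @slot cdsComplete logical; when TRUE the total CDS length must be a
#'   multiple of 3.
#'
#' @export
setClass("GeneModel",
  representation(
    geneId = "character",
    chrom = "character",
    subgenome = "character",
    strand = "character",
    exons = "IRanges",
    cds = "IRanges",
    transcriptIds = "character",
    cdsComplete = "logical"
  ),
  prototype(subgenome = "U", strand = "+", cdsComplete = FALSE)
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  if (!object@subgenome %in% c("A", "B", "D", "U"))
    msg <- c(msg, "subgenome must be one of A, B, D, U")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  chk <- function(ir, what) {
    out <- character()
    if (length(ir)) {
      if (any(width(ir) < 1L))
        out <- c(out, sprintf("%s intervals must have positive width", what))
      if (is.unsorted(start(ir)))
        out <- c(out, sprintf("%s intervals must be sorted ascending", what))
      if (length(reduce(ir, min.gapwidth = 0L)) != length(ir))
        out <- c(out, sprintf("%s intervals must be non-overlapping", what))
    }
    out
  }
  msg <- c(msg, chk(object@exons, "exon"), chk(object@cds, "cds"))
  if (length(object@cds)) {
    exu <- reduce(object@exons)
    cov <- IRanges::countOverlaps(object@cds, exu, type = "within")
    if (any(cov == 0L))
      msg <- c(msg, "every CDS interval must be contained in the exon union")
    if (isTRUE(object@cdsComplete) && sum(width(object@cds)) %% 3L != 0L)
      msg <- c(msg, "complete CDS length must be a multiple of 3")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param chrom chromosome token; the subgenome is taken from its trailing
#'   letter (\code{...A}, \code{...B}, \code{...D}), anything else is
#'   unanchored (\code{"U"}).
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons,cds \linkS4class{IRanges} of genomic intervals (1-based
#'   closed).
#' @param transcriptIds character vector of transcript ids.
#' @param cdsComplete logical; assert that the CDS is a complete ORF.
#' @return a \linkS4class{GeneModel}.
#' @export
GeneModel <- function(geneId, chrom, strand = "+", exons = IRanges(),
                      cds = IRanges(), transcriptIds = character(),
                      cdsComplete = FALSE) {
  new("GeneModel", geneId = geneId, chrom = chrom,
      subgenome = subgenomeOf(chrom), strand = strand,
      exons = exons[order(start(exons))], cds = cds[order(start(cds))],
      transcriptIds = transcriptIds, cdsComplete = cdsComplete)
}

#' Subgenome from a chromosome token
#'
#' The trailing letter of the chromosome name assigns the subgenome
#' (\code{"7A"} -> A); unmatched tokens (e.g. \code{"Un"}) are unanchored
#' (\code{"U"}).
#'
#' @param chrom character vector of chromosome tokens.
#' @return character vector over \code{c("A","B","D","U")}.
#' @export
subgenomeOf <- function(chrom) {
  last <- toupper(substring(chrom, nchar(chrom)))
  ifelse(last %in% c("A", "B", "D"), last, "U")
}

#' @describeIn GeneModel-class gene id accessor
#' @param object,x a \code{GeneModel}
#' @export
geneId <- function(x) x@geneId

#' @describeIn GeneModel-class exon intervals accessor
#' @export
exons <- function(x) x@exons

#' @describeIn GeneModel-class CDS intervals accessor
#' @export
cdsRanges <- function(x) x@cds

#' @describeIn GeneModel-class subgenome accessor
#' @export
subgenome <- function(x) x@subgenome

#' @describeIn GeneModel-class transcript ids accessor
#' @export
transcriptIds <- function(x) x@transcriptIds

setMethod("show", "GeneModel", function(object) {
  cat(sprintf(
    "GeneModel %s | %s (%s) strand %s | %d exon(s), %d CDS segment(s), %d transcript(s)\n",
    object@geneId, object@chrom, object@subgenome, object@strand,
    length(object@exons), length(object@cds), length(object@transcriptIds)))
})

#' HomoeologueTriplet: linked A/B/D copies of one candidate locus
#'
#' Holds up to three homoeologous gene models together with their genomic
#' sequences, keyed by subgenome.
#'
#' @slot label triplet label (candidate name).
#' @slot models named list of \linkS4class{GeneModel}, names in
#'   \code{c("A","B","D","U")}, distinct.
#' @slot seqs \code{DNAStringSet} of the members' genomic sequences, same
#'   names and order as \code{models}.
#' @slot setCode subset string over \code{"ABDU"} (e.g. the significance
#'   code carried from DE triage).
#' @export
setClass("HomoeologueTriplet",
  representation(
    label = "character",
    models = "list",
    seqs = "DNAStringSet",
    setCode = "character"
  ),
  prototype(setCode = "")
)

setValidity("HomoeologueTriplet", function(object) {
  msg <- character()
  n <- length(object@models)
  if (n < 1L || n > 3L)
    msg <- c(msg, "a triplet must have 1-3 members")
  nm <- names(object@models)
  if (is.null(nm) || !all(nm %in% c("A", "B", "D", "U")) || anyDuplicated(nm))
    msg <- c(msg, "members must be named by distinct subgenomes (A/B/D/U)")
  if (!identical(nm, names(object@seqs)))
    msg <- c(msg, "models and seqs must share names and order")
  if (!all(vapply(object@models, is, logical(1), class2 = "GeneModel")))
    msg <- c(msg, "all members must be GeneModel objects")
  if (length(msg)) msg else TRUE
})

#' Construct a HomoeologueTriplet
#'
#' @param label candidate label.
#' @param models named list of \linkS4class{GeneModel} (names = subgenomes).
#' @param seqs \code{DNAStringSet} of member genomic sequences, same names.
#' @param setCode significance subset code over \code{"ABDU"}.
#' @return a \linkS4class{HomoeologueTriplet}.
#' @export
HomoeologueTriplet <- function(label, models, seqs, setCode = "") {
  new("HomoeologueTriplet", label = label, models = models,
      seqs = seqs, setCode = setCode)
}

#' @describeIn HomoeologueTriplet-class member gene models
#' @param x a \code{HomoeologueTriplet}
#' @export
tripletModels <- function(x) x@models

#' @describeIn HomoeologueTriplet-class member genomic sequences
#' @export
tripletSeqs <- function(x) x@seqs

#' @describeIn HomoeologueTriplet-class candidate label
#' @export
tripletLabel <- function(x) x@label

setMethod("show", "HomoeologueTriplet", function(object) {
  cat(sprintf("HomoeologueTriplet '%s' with %d member(s): %s\n",
              object@label, length(object@models),
              paste(names(object@models), collapse = ", ")))
  for (sg in names(object@models))
    cat(sprintf("  [%s] %s (%d bp)\n", sg, geneId(object@models[[sg]]),
                length(object@seqs[[sg]])))
})
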