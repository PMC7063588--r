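#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement DNAString subseq
NULL

#' Read a multi-record FASTA file
#'
#' Wraps \code{Biostrings::readDNAStringSet} with the package's ingest
#' contract: sequences are uppercased, record order is preserved, headers are
#' truncated at the first whitespace, and duplicate ids or empty sequences
#' are errors naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}.
#' @export
readFastaRecords <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- readDNAStringSet(path, format = "fasta")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(names(seqs))))
    stop("FASTA format error: record with empty header in ", path)
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("FASTA format error: duplicated record id(s): ",
         paste(dup, collapse = ", "))
  empty <- names(seqs)[Biostrings::width(seqs) == 0L]
  if (length(empty))
    stop("FASTA format error: empty sequence for record(s): ",
         paste(empty, collapse = ", "))
  DNAStringSet(toupper(as.character(seqs)))
}

#' Write sequences to FASTA
#'
#' Deterministic writer paired with \code{\link{readFastaRecords}}: records
#' are emitted in input order.
#'
#' @param seqs named \code{DNAStringSet} (or named character vector).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFastaRecords <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features into \linkS4class{GeneModel} objects.
#' Exons and CDS are grouped per transcript and transcripts per gene; the
#' first transcript of each gene is the representative whose structure is
#' stored (splice variants collapse to one locus). The subgenome is inferred
#' from the chromosome token's trailing letter.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates per the
#'   standard; stored unchanged as 1-based closed IRanges).
#' @return named list of \linkS4class{GeneModel}, in file order of the gene
#'   features.
#' @export
readGFF3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  strd <- as.character(GenomicRanges::strand(gr))
  if (any(type %in% c("gene", "mRNA") & !strd %in% c("+", "-")))
    stop("GFF3 format error: unknown strand symbol for a gene/mRNA feature")
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))

  genes <- which(type == "gene")
  out <- vector("list", length(genes))
  names(out) <- ids[genes]
  for (k in seq_along(genes)) {
    gi <- genes[k]
    gid <- ids[gi]
    tx <- which(type == "mRNA" & parents == gid)
    txIds <- ids[tx]
    if (!length(tx))
      stop("GFF3 model error: gene ", gid, " has no mRNA feature")
    rep_tx <- txIds[1]
    exi <- which(type == "exon" & parents == rep_tx)
    cdi <- which(type == "CDS" & parents == rep_tx)
    exr <- IRanges(GenomicRanges::start(gr)[exi], GenomicRanges::end(gr)[exi])
    cdr <- IRanges(GenomicRanges::start(gr)[cdi], GenomicRanges::end(gr)[cdi])
    exr <- exr[order(start(exr))]
    cdr <- cdr[order(start(cdr))]
    if (length(cdr)) {
      within <- IRanges::countOverlaps(cdr, reduce(exr), type = "within")
      if (any(within == 0L))
        stop("GFF3 model error: CDS outside exon union for gene ", gid)
    }
    out[[k]] <- GeneModel(
      geneId = gid,
      chrom = as.character(GenomicRanges::seqnames(gr))[gi],
      strand = strd[gi],
      exons = exr, cds = cdr, transcriptIds = txIds,
      cdsComplete = length(cdr) > 0 && sum(width(cdr)) %% 3L == 0L)
  }
  out
}

#' Write gene models to GFF3
#'
#' Deterministic writer paired with \code{\link{readGFF3}} (input order;
#' one mRNA per stored representative structure plus any additional
#' transcript ids as structure-less mRNA lines are NOT emitted -- only the
#' representative transcript round-trips structurally, additional ids are
#' kept as extra mRNA features sharing the representative's span).
#'
#' @param models list of \linkS4class{GeneModel}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGFF3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- range(c(start(m@exons), end(m@exons)))
    line <- function(type, s, e, attrs)
      sprintf("%s\twheatGMS\t%s\t%d\t%d\t.\t%s\t.\t%s",
              m@chrom, type, s, e, m@strand, attrs)
    writeLines(line("gene", span[1], span[2],
                    sprintf("ID=%s", m@geneId)), con)
    for (i in seq_along(m@transcriptIds))
      writeLines(line("mRNA", span[1], span[2],
                      sprintf("ID=%s;Parent=%s", m@transcriptIds[i],
                              m@geneId)), con)
    rep_tx <- m@transcriptIds[1]
    for (i in seq_along(m@exons))
      writeLines(line("exon", start(m@exons)[i], end(m@exons)[i],
                      sprintf("ID=%s.exon%d;Parent=%s", rep_tx, i, rep_tx)),
                 con)
    for (i in seq_along(m@cds))
      writeLines(line("CDS", start(m@cds)[i], end(m@cds)[i],
                      sprintf("ID=%s.cds%d;Parent=%s", rep_tx, i, rep_tx)),
                 con)
  }
  invisible(path)
}

#' Extract the spliced CDS of a gene model
#'
#' Concatenates the CDS intervals in ascending genomic order and
#' reverse-complements the result for minus-strand genes, so the returned
#' sequence starts at the ORF's first base and is translatable in frame 0.
#'
#' @param model a \linkS4class{GeneModel} with non-empty CDS.
#' @param genomeSeq a \code{DNAString}/\code{DNAStringSet} element or
#'   character string holding the genomic sequence the model's coordinates
#'   refer to.
#' @return a \code{DNAString} with the spliced CDS.
#' @export
extractCDS <- function(model, genomeSeq) {
  if (!length(model@cds)) stop("gene model ", model@geneId, " has no CDS")
  s <- as.character(genomeSeq)
  if (max(end(model@cds)) > nchar(s))
    stop("range error: CDS interval exceeds sequence bounds for ",
         model@geneId)
  parts <- substring(s, start(model@cds), end(model@cds))
  cds <- DNAString(paste(parts, collapse = ""))
  if (model@strand == "-") cds <- reverseComplement(cds)
  cds
}

#' Reverse-complement helper for character sequences
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}
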