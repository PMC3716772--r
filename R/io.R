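#' Read and write the package's standard file formats
#'
#' Thin wrappers around Biostrings / rtracklayer and base R used across all
#' modules.  Coordinates in every table and file are 1-based inclusive (the
#' GFF3 convention); strand is "+" or "-".
#'
#' @name panforge-io
NULL

#' Write a gene table as GFF3
#'
#' Emits `CDS` features, 1-based inclusive coordinates, with `ID` (gene id)
#' attributes.  One file per (strain, predictor) track is the convention
#' used by the consensus caller.
#'
#' @param genes data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `gene_id`, and optionally `source` (predictor name).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  src <- if ("source" %in% names(genes)) genes$source else "panforge"
  if (nrow(genes) > 0) {
    o <- order(genes$contig, genes$start, genes$end, genes$strand)
    genes <- genes[o, , drop = FALSE]
    if (length(src) > 1) src <- src[o]
    gr <- GenomicRanges::GRanges(
      seqnames = genes$contig,
      ranges = IRanges::IRanges(start = genes$start, end = genes$end),
      strand = genes$strand)
    S4Vectors::mcols(gr)$source <- src
    S4Vectors::mcols(gr)$type <- "CDS"
    S4Vectors::mcols(gr)$phase <- 0L
    S4Vectors::mcols(gr)$ID <- genes$gene_id
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 gene track
#'
#' Parses `CDS` features (via rtracklayer) into the package's gene table
#' layout.  Only the columns the pipeline uses are retained.
#'
#' @param path GFF3 file.
#' @return data.frame with `contig`, `start`, `end`, `strand`, `gene_id`,
#'   `source`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (length(gr) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  mc <- S4Vectors::mcols(gr)
  src <- if ("source" %in% names(mc)) as.character(mc$source) else "unknown"
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = as.character(mc$ID),
             source = src, stringsAsFactors = FALSE)
}

#' @rdname panforge-io
#' @param x named character vector or XStringSet.
#' @param path file path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    x <- Biostrings::BStringSet(x)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname panforge-io
#' @param type "DNA" or "AA".
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (type == "DNA") Biostrings::readDNAStringSet(path)
  else Biostrings::readAAStringSet(path)
}

#' @rdname panforge-io
#' @param df data.frame.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname panforge-io
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "")
}
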