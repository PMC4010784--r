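#' Read and write FASTA sequence sets
#'
#' Thin wrappers around Biostrings keeping the package's working
#' representation (a named character vector) at the boundaries.
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(x)
  names(s) <- names(x)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read and write FASTQ read sets
#'
#' Reads are adapter-free small RNA sequences; qualities are not used by the
#' pipeline, so writing emits a constant dummy quality ("I").
#'
#' @param path file path.
#' @param reads character vector of read sequences.
#' @param ids optional read identifiers.
#' @return `read_fastq` returns an unnamed character vector of sequences.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  unname(as.character(s))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%08d", seq_along(reads))
  s <- Biostrings::DNAStringSet(reads)
  names(s) <- ids
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read and write GFF3 feature tables
#'
#' Features are held internally as a `data.table` with 0-based half-open
#' coordinates and columns `chrom, start, end, strand, type, ID`; conversion
#' to/from GFF3's 1-based inclusive convention happens here, via rtracklayer.
#'
#' @param path file path.
#' @param features feature `data.table` (0-based half-open).
#' @return `read_gff3` returns a feature `data.table`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    ID = as.character(gr$ID))
}

#' @rdname read_gff3
#' @export
write_gff3 <- function(features, path) {
  stopifnot(all(c("chrom", "start", "end", "strand", "type", "ID") %in%
                  names(features)))
  strand <- ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = strand)
  gr$type <- features$type
  gr$ID <- features$ID
  gr$source <- "srnablocks"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Feature table as GRanges (1-based) for overlap queries
#' @keywords internal
features_as_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = "*", type = features$type, ID = features$ID)
}

#' Write/read a plain TSV table
#' @param x a data.frame.
#' @param path file path.
#' @return `read_tsv` returns a `data.table`.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) data.table::fread(path, sep = "\t")
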