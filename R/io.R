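#' Read and write FASTA files
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] that return/accept plain named character
#' vectors, the sequence container used throughout panquant. Sequences are
#' uppercased on read; on write they are wrapped at 60 columns.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read and write paired FASTQ files
#'
#' Reads are written with a constant 'I' (Q40, Sanger scale) quality string,
#' matching an error-free simulation.
#'
#' @param pairs a `read_pairs` object from [simulate_reads()], or a list with
#'   character vectors `id`, `mate1`, `mate2`.
#' @param prefix output prefix; `<prefix>_1.fastq` and `<prefix>_2.fastq` are
#'   written.
#' @return `write_fastq()`: the two paths, invisibly. `read_fastq()`: a list
#'   with `id`, `mate1`, `mate2`.
#' @export
write_fastq <- function(pairs, prefix) {
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(pairs[[paste0("mate", m)]])
    names(seqs) <- paste0(pairs$id, "/", m)
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, paste0(prefix, "_", m, ".fastq"),
                                format = "fastq", qualities = qual)
  }
  invisible(paste0(prefix, "_", 1:2, ".fastq"))
}

#' @param path1,path2 the two mate FASTQ files.
#' @rdname write_fastq
#' @export
read_fastq <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(r1) != length(r2))
    stop("mate files have different numbers of records")
  list(id = sub("/1$", "", sub("\\s.*$", "", names(r1))),
       mate1 = unname(as.character(r1)), mate2 = unname(as.character(r2)))
}

#' Read and write BED intervals
#'
#' BED records are 0-based half-open. `read_bed()` validates that
#' `start < end` and reports the offending line on failure.
#'
#' @param path file path.
#' @return a data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  bad <- which(!(x$start < x$end))
  if (length(bad))
    stop("BED record with start >= end at line ", bad[1], " of ", path)
  x
}

#' @param bed data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optional further columns.
#' @rdname read_bed
#' @export
write_bed <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  if (any(bed$start >= bed$end)) stop("BED record with start >= end")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write tab-separated tables
#'
#' UTF-8, header row, no quoting; the on-disk format for all panquant tables.
#'
#' @param path file path.
#' @return `read_tsv()`: a data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, quote = "", check.names = FALSE)
}

#' @param x data frame.
#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
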