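# Thin wrappers around Biostrings for the file formats the pipeline touches.
# Sequences move through the package as plain named character vectors; the
# XStringSet containers are used at the I/O and alignment boundaries only.

#' Read / write FASTA
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @rdname fasta_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @param seqs named character vector.
#' @rdname fasta_io
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write FASTQ
#'
#' Qualities are constant ("I") on write; they are ignored on read — the
#' validation model is substitution-only and quality-blind.
#'
#' @param path file path (plain or gzipped).
#' @rdname fastq_io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @param reads named character vector of read sequences.
#' @rdname fastq_io
#' @export
write_fastq <- function(reads, path) {
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
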