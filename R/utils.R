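# Internal helpers shared across modules. Sequences are handled as plain
# uppercase character strings with the DNA alphabet (T internally; U is
# converted at I/O boundaries, since genomes are DNA and miRNA catalogs RNA).

#' Convert between RNA (U) and internal DNA (T) representation
#'
#' @param x Character vector of sequences.
#' @return Uppercase sequences with U replaced by T (`to_dna`) or T by U
#'   (`to_rna`).
#' @export
to_dna <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)

#' @rdname to_dna
#' @export
to_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Write reads as FASTQ with constant dummy qualities
#'
#' The pipeline's filters are sequence-based (no quality trimming), so
#' simulated reads carry a constant Phred+33 quality of "I" (Q40).
#'
#' @param reads Named character vector of read sequences (names become read
#'   identifiers).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(unname(reads))
  names(dss) <- names(reads)
  qual <- Biostrings::BStringSet(vapply(width_of(reads), function(w) {
    strrep("I", w)
  }, character(1)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a character vector of sequences
#'
#' @param path FASTQ file path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(dss))
  names(out) <- names(dss)
  out
}

width_of <- function(x) nchar(x)

#' Write a named set of sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(to_dna(unname(seqs)))
  names(dss) <- names(seqs)
  Biostrings::writeXStringSet(dss, path, format = "fasta")
  invisible(path)
}

#' Read FASTA into a named character vector (U converted to T)
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- to_dna(as.character(dss))
  names(out) <- sub("\\s.*$", "", names(dss))
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
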