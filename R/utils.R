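# Sequence and IO helpers shared across modules. All user-facing coordinates
# are 0-based half-open; conversion to R's 1-based substr() happens here.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring in 0-based half-open coordinates
substr0 <- function(x, start, end) {
  substring(x, start + 1L, end)
}

# Encode integer Phred scores (possibly a list or a single vector) as
# Phred+33 strings. `scores` is an integer vector, `widths` splits it into
# per-read runs.
phred_encode <- function(scores, widths = length(scores)) {
  stopifnot(sum(widths) == length(scores))
  big <- rawToChar(as.raw(as.integer(scores) + 33L))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  substring(big, starts, ends)
}

# Decode a vector of Phred+33 strings into a list of integer vectors.
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

# Draw n i.i.d. bases with the given probabilities over A,C,G,T.
random_bases <- function(n, prob) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), sequence = unname(as.character(x)))
}

#' Write sequences from a tibble to FASTA
#'
#' @param x A data frame with an identifier column and a `sequence` column.
#' @param path Output path.
#' @param id_col Name of the identifier column (default first column).
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(x, path, id_col = names(x)[1]) {
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- x[[id_col]]
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to a (optionally gzipped) FASTQ file (Phred+33).
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write reads from a tibble to FASTQ
#'
#' @param x A data frame with columns `read_id`, `sequence`, `quality`.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq_tbl <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- x$read_id
  Biostrings::writeXStringSet(
    seqs, path,
    format = "fastq",
    qualities = Biostrings::BStringSet(x$quality),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Read a tab-separated table with a header
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a tab-separated table with a header
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
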