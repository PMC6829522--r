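# Per-scaffold features: GC content, canonical tetranucleotide frequencies,
# per-sample mean coverage, and assembly statistics. These are the
# coordinates in which binning and refinement operate.

# GC fraction without validity checks (internal fast path)
gc_fraction <- function(x) {
  s <- Biostrings::DNAStringSet(x)
  gc <- Biostrings::letterFrequency(s, letters = c("G", "C"))
  acgt <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  rowSums(gc) / rowSums(acgt)
}

#' GC fraction of sequences
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases (N etc.) are excluded from
#' both numerator and denominator.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Numeric vector of GC fractions.
#' @export
compute_gc <- function(sequence) {
  if (length(sequence) == 0 || any(!nzchar(sequence))) {
    abort("cannot compute GC of an empty sequence")
  }
  gc <- gc_fraction(sequence)
  if (any(!is.finite(gc))) abort("sequence has no unambiguous bases")
  gc
}

#' Canonical tetranucleotide keys
#'
#' The 256 4-mers pooled with their reverse complements give 136 canonical
#' keys (the lexicographically smaller of each pair; the 16 reverse-
#' complement palindromes map to themselves). Assembled scaffolds are
#' strandless, so composition features must be strand-symmetric.
#'
#' @return Character vector of the 136 canonical 4-mers, sorted.
#' @export
tnf_keys <- function() {
  words <- Biostrings::mkAllStrings(DNA_BASES, 4)
  sort(unique(pmin(words, revcomp(words))))
}

#' Canonical tetranucleotide frequency vectors
#'
#' Slides a 4-base window one base at a time (windows containing ambiguous
#' bases are skipped), pools each 4-mer with its reverse complement into one
#' of the 136 canonical keys, and normalizes counts to frequencies.
#'
#' @param sequence Character vector of sequences (each of length >= 4 with
#'   at least one unambiguous 4-mer).
#' @return For a single sequence, a named 136-vector; otherwise a matrix
#'   (sequences x 136), rows named after `names(sequence)`.
#' @export
compute_tnf <- function(sequence) {
  if (length(sequence) == 0) abort("no sequences given")
  if (any(nchar(sequence) < 4)) abort("sequences must be at least 4 bases long")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequence), width = 4
  )
  words <- colnames(counts)
  canon <- pmin(words, revcomp(words))
  collapsed <- t(rowsum(t(counts), group = canon))
  tot <- rowSums(collapsed)
  if (any(tot == 0)) abort("sequence has no unambiguous 4-mer window")
  out <- collapsed / tot
  rownames(out) <- names(sequence)
  if (length(sequence) == 1) out[1, ] else out
}

#' Mean read depth per scaffold from an alignment table
#'
#' Mean depth is the total aligned bases on a scaffold divided by its
#' length (equivalent in expectation to a per-base pileup, in one pass).
#' Scaffolds with no alignments get depth 0.
#'
#' @param alignments Alignment tibble with columns `scaffold_id` and
#'   `aligned_bases` (optionally `sample_id`).
#' @param scaffold_lengths Tibble (`scaffold_id`, `length`) or a named
#'   integer vector.
#' @param sample_id Optional: restrict `alignments` to one sample.
#' @return Tibble (`scaffold_id`, `depth`) in `scaffold_lengths` order.
#' @export
compute_coverage <- function(alignments, scaffold_lengths, sample_id = NULL) {
  if (!is.data.frame(scaffold_lengths)) {
    scaffold_lengths <- tibble(scaffold_id = names(scaffold_lengths),
                               length = as.numeric(scaffold_lengths))
  }
  if (!is.null(sample_id)) {
    alignments <- alignments[alignments$sample_id == sample_id, ]
  }
  unknown <- setdiff(alignments$scaffold_id, scaffold_lengths$scaffold_id)
  if (length(unknown)) {
    abort(paste0("alignments reference unknown scaffolds: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  totals <- alignments |>
    group_by(.data$scaffold_id) |>
    summarise(aligned = sum(.data$aligned_bases), .groups = "drop")
  scaffold_lengths |>
    left_join(totals, by = "scaffold_id") |>
    mutate(depth = dplyr::coalesce(.data$aligned, 0) / .data$length) |>
    select("scaffold_id", "depth")
}

#' Per-scaffold coverage matrix across samples
#'
#' @param alignments Alignment tibble with a `sample_id` column.
#' @param scaffold_lengths Tibble (`scaffold_id`, `length`) or named vector.
#' @param sample_ids Samples to include, in column order (default: all, in
#'   order of appearance).
#' @return Tibble with `scaffold_id` and one mean-depth column per sample.
#' @export
coverage_matrix <- function(alignments, scaffold_lengths, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(alignments$sample_id)
  out <- NULL
  for (s in sample_ids) {
    cov <- compute_coverage(alignments, scaffold_lengths, sample_id = s) |>
      rename(!!s := "depth")
    out <- if (is.null(out)) cov else left_join(out, cov, by = "scaffold_id")
  }
  out
}

#' N50 of a set of scaffold lengths
#'
#' The largest length L such that scaffolds of length >= L together cover
#' at least half the total assembly length.
#'
#' @param lengths Non-empty vector of positive lengths.
#' @return The N50, in bases.
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) abort("N50 of an empty length set is undefined")
  if (any(lengths <= 0)) abort("scaffold lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Filter scaffolds by minimum length
#'
#' @param scaffolds Data frame with a `length` column (computed from
#'   `sequence` if absent). Order is preserved; the boundary is inclusive.
#' @param min_len Minimum length in bases (default 1000).
#' @return The surviving rows.
#' @export
filter_scaffolds <- function(scaffolds, min_len = 1000) {
  len <- if ("length" %in% names(scaffolds)) scaffolds$length else nchar(scaffolds$sequence)
  scaffolds[len >= min_len, , drop = FALSE]
}

#' Per-scaffold profile table
#'
#' @param scaffolds Data frame with `scaffold_id` and `sequence`.
#' @param alignments Optional alignment tibble with `sample_id`; adds one
#'   mean-depth column per sample.
#' @return Tibble `scaffold_id`, `length`, `gc` (+ coverage columns).
#' @export
scaffold_profiles <- function(scaffolds, alignments = NULL) {
  prof <- tibble(
    scaffold_id = scaffolds$scaffold_id,
    length = nchar(scaffolds$sequence),
    gc = compute_gc(scaffolds$sequence)
  )
  if (!is.null(alignments)) {
    prof <- left_join(
      prof,
      coverage_matrix(alignments, prof[, c("scaffold_id", "length")]),
      by = "scaffold_id"
    )
  }
  prof
}
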