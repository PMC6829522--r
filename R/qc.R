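# Native read trimming with the usual survey-sequencing rules: adapter
# clipping, low-quality end cutting, sliding-window truncation, and a
# minimum-length drop. Semantics follow the standard SLIDINGWINDOW trimmer
# convention: windows advance one base at a time and the read is truncated
# at the start of the first failing window; trailing windows shorter than
# the window size are evaluated on their actual length.

#' Read-trimming policy
#'
#' Defaults mirror common practice for Illumina survey data: cut leading and
#' trailing bases below Phred 3, truncate at the first 4-base window whose
#' mean quality drops below 20, and drop reads shorter than 50 bases.
#'
#' @param end_quality_floor Phred floor for leading/trailing base removal.
#' @param window_size Sliding-window width in bases (>= 1).
#' @param window_mean_floor Phred floor for the window mean.
#' @param min_length Minimum surviving read length.
#' @param adapters Character vector of adapter sequences (exact-match
#'   clipping; default none).
#' @return A `trim_policy` object.
#' @export
trim_policy <- function(end_quality_floor = 3, window_size = 4,
                        window_mean_floor = 20, min_length = 50,
                        adapters = character()) {
  stopifnot(end_quality_floor >= 0, window_size >= 1,
            window_mean_floor >= 0, min_length >= 0)
  structure(
    list(end_quality_floor = end_quality_floor, window_size = window_size,
         window_mean_floor = window_mean_floor, min_length = min_length,
         adapters = toupper(adapters)),
    class = "trim_policy"
  )
}

# earliest 0-based clip point for adapter read-through at the 3' end:
# either a full adapter occurrence, or a read suffix equal to an adapter
# prefix of at least `min_overlap` bases
adapter_clip_point <- function(seq, adapters, min_overlap = 8) {
  n <- nchar(seq)
  cut <- n
  for (ad in adapters) {
    hit <- regexpr(ad, seq, fixed = TRUE)[1]
    if (hit > 0) cut <- min(cut, hit - 1L)
    max_ov <- min(nchar(ad), n)
    for (L in max_ov:min_overlap) {
      if (L > n) next
      if (substr(seq, n - L + 1L, n) == substr(ad, 1L, L)) {
        cut <- min(cut, n - L)
        break
      }
    }
  }
  cut
}

# trimming core on an integer quality vector; returns kept range [from, to]
# (1-based inclusive) or c(1, 0) when nothing survives. The end-cut and
# window rules are reapplied after each truncation until the read is stable
# (truncation exposes new, shorter trailing windows), which makes trimming
# idempotent.
trim_range <- function(q, policy, n_adapter_cut = length(q)) {
  to <- n_adapter_cut
  from <- 1L
  w <- policy$window_size
  repeat {
    old_from <- from
    old_to <- to
    while (from <= to && q[from] < policy$end_quality_floor) from <- from + 1L
    while (to >= from && q[to] < policy$end_quality_floor) to <- to - 1L
    if (from > to) return(c(1L, 0L))
    qs <- q[from:to]
    len <- length(qs)
    cs <- c(0, cumsum(qs))
    ends <- pmin(seq_len(len) + w - 1L, len)
    means <- (cs[ends + 1L] - cs[seq_len(len)]) / (ends - seq_len(len) + 1L)
    bad <- which(means < policy$window_mean_floor)
    if (length(bad)) to <- from + bad[1] - 2L
    if (from > to) return(c(1L, 0L))
    if (from == old_from && to == old_to) break
  }
  c(from, to)
}

#' Trim a single read
#'
#' Applies, in order: optional adapter clipping, removal of leading then
#' trailing bases below the end-quality floor, truncation at the start of
#' the first sliding window whose mean quality falls below the window
#' floor, and a minimum-length drop. End cutting and window truncation are
#' reapplied until the kept range is stable (each truncation exposes new,
#' shorter trailing windows), so trimming is idempotent.
#'
#' @param sequence Nucleotide string.
#' @param qualities Integer Phred scores (one per base) or a Phred+33
#'   string of the same length.
#' @param policy A [trim_policy()].
#' @return A list: `sequence`, `qualities` (same type as the input), and
#'   `dropped` (TRUE when the trimmed read is shorter than `min_length`).
#' @export
trim_read <- function(sequence, qualities, policy = trim_policy()) {
  as_string <- is.character(qualities) && length(qualities) == 1 &&
    nchar(qualities) == nchar(sequence) && nchar(sequence) != 1
  q <- if (is.character(qualities)) utf8ToInt(qualities) - 33L else as.integer(qualities)
  if (length(q) != nchar(sequence)) {
    abort("sequence and qualities have different lengths")
  }
  cut <- if (length(policy$adapters)) {
    adapter_clip_point(sequence, policy$adapters)
  } else {
    nchar(sequence)
  }
  r <- trim_range(q, policy, cut)
  s <- substr(sequence, r[1], r[2])
  qq <- if (r[2] >= r[1]) q[r[1]:r[2]] else integer(0)
  list(
    sequence = s,
    qualities = if (as_string) intToUtf8(qq + 33L) else qq,
    dropped = nchar(s) < policy$min_length
  )
}

# vectorized trim over a read tibble; returns the tibble with trimmed
# sequence/quality and a `dropped` column
trim_tbl <- function(x, policy) {
  n <- nrow(x)
  if (n == 0) return(mutate(x, dropped = logical(0)))
  qlen <- nchar(x$quality)
  if (any(qlen != nchar(x$sequence))) {
    abort("sequence and qualities have different lengths")
  }
  # fast path: a read whose every base is at or above both floors is
  # untouched by end-cutting and window truncation
  floor_all <- max(policy$end_quality_floor, policy$window_mean_floor)
  slow <- rep(TRUE, n)
  if (length(policy$adapters) == 0 && length(unique(qlen)) == 1) {
    qm <- matrix(utf8ToInt(paste(x$quality, collapse = "")) - 33L,
                 ncol = qlen[1], byrow = TRUE)
    mins <- qm[, 1]
    for (j in seq_len(ncol(qm))[-1]) mins <- pmin(mins, qm[, j])
    slow <- mins < floor_all
  }
  seqs <- x$sequence
  quals <- x$quality
  dropped <- nchar(seqs) < policy$min_length
  for (i in which(slow)) {
    tr <- trim_read(seqs[i], quals[i], policy)
    seqs[i] <- tr$sequence
    quals[i] <- if (is.character(tr$qualities)) {
      tr$qualities
    } else {
      intToUtf8(as.integer(tr$qualities) + 33L)
    }
    dropped[i] <- tr$dropped
  }
  x$sequence <- seqs
  x$quality <- quals
  x$dropped <- dropped
  x
}

#' Trim mate-synchronized paired reads
#'
#' Pairs where both mates survive stay paired; single survivors go to the
#' orphan stream; a summary records counts per category.
#'
#' @param r1,r2 Read tibbles (`read_id`, `sequence`, `quality`) or FASTQ
#'   paths. Must be mate-synchronized (same reads, same order).
#' @param policy A [trim_policy()].
#' @return A list: `pairs` (tibble `read_id`, `sequence1`, `quality1`,
#'   `sequence2`, `quality2`), `orphans` (tibble `read_id`, `mate`,
#'   `sequence`, `quality`), and `counts` (tibble of categories
#'   `both_surviving`, `forward_only`, `reverse_only`, `dropped`).
#' @export
trim_pairs <- function(r1, r2, policy = trim_policy()) {
  if (is.character(r1)) r1 <- read_fastq_tbl(r1)
  if (is.character(r2)) r2 <- read_fastq_tbl(r2)
  if (nrow(r1) != nrow(r2) || !identical(strip_mate(r1$read_id), strip_mate(r2$read_id))) {
    abort("mate files are desynchronized")
  }
  t1 <- trim_tbl(r1, policy)
  t2 <- trim_tbl(r2, policy)
  keep1 <- !t1$dropped
  keep2 <- !t2$dropped
  both <- keep1 & keep2
  pairs <- tibble(
    read_id = t1$read_id[both],
    sequence1 = t1$sequence[both], quality1 = t1$quality[both],
    sequence2 = t2$sequence[both], quality2 = t2$quality[both]
  )
  orphans <- bind_rows(
    tibble(read_id = t1$read_id[keep1 & !keep2], mate = 1L,
           sequence = t1$sequence[keep1 & !keep2],
           quality = t1$quality[keep1 & !keep2]),
    tibble(read_id = t2$read_id[!keep1 & keep2], mate = 2L,
           sequence = t2$sequence[!keep1 & keep2],
           quality = t2$quality[!keep1 & keep2])
  )
  counts <- tibble(
    category = c("both_surviving", "forward_only", "reverse_only", "dropped"),
    n = c(sum(both), sum(keep1 & !keep2), sum(!keep1 & keep2), sum(!keep1 & !keep2))
  )
  list(pairs = pairs, orphans = orphans, counts = counts)
}

# tolerate "/1", "/2" or " 1:..." style mate decorations when checking sync
strip_mate <- function(ids) sub("[/ ][12].*$", "", ids)
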