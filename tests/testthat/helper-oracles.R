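# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops and base R only, so they can arbitrate the
# vectorized implementations.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_gc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
}

oracle_tnf <- function(seq) {
  words <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1, paste, collapse = "")
  keys <- sort(unique(vapply(words, function(w) min(w, oracle_revcomp(w)), character(1))))
  counts <- setNames(rep(0, length(keys)), keys)
  n <- nchar(seq)
  for (i in seq_len(n - 3)) {
    w <- substr(seq, i, i + 3)
    if (grepl("[^ACGT]", w)) next
    key <- min(w, oracle_revcomp(w))
    counts[key] <- counts[key] + 1
  }
  counts / sum(counts)
}

# per-base pileup from explicit read placements
oracle_pileup_coverage <- function(placements, scaffold_lengths) {
  out <- numeric(length(scaffold_lengths))
  names(out) <- names(scaffold_lengths)
  depth <- lapply(scaffold_lengths, function(L) numeric(L))
  for (i in seq_len(nrow(placements))) {
    sid <- placements$scaffold_id[i]
    pos <- placements$start[i] + seq_len(placements$len[i])
    depth[[sid]][pos] <- depth[[sid]][pos] + 1
  }
  vapply(names(scaffold_lengths), function(sid) mean(depth[[sid]]), numeric(1))
}

oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
}

oracle_gc_hist <- function(gc, weight, bin_width = 1) {
  bins <- list()
  for (i in seq_along(gc)) {
    b <- as.character(floor(gc[i] * 100 / bin_width) * bin_width)
    bins[[b]] <- (bins[[b]] %||% 0) + weight[i]
  }
  v <- unlist(bins)
  v <- v / sum(v)
  v[order(as.numeric(names(v)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent re-implementation of the trimming rules (no adapters): end
# cutting and window truncation are looped until the kept range is stable
oracle_trim <- function(seq, q, policy) {
  keep <- seq_along(q)
  repeat {
    before <- length(keep)
    while (length(keep) && q[keep[1]] < policy$end_quality_floor) keep <- keep[-1]
    while (length(keep) && q[keep[length(keep)]] < policy$end_quality_floor) {
      keep <- keep[-length(keep)]
    }
    qs <- q[keep]
    cutlen <- length(qs)
    for (k in seq_along(qs)) {
      win <- qs[k:min(k + policy$window_size - 1, length(qs))]
      if (mean(win) < policy$window_mean_floor) {
        cutlen <- k - 1
        break
      }
    }
    keep <- keep[seq_len(cutlen)]
    if (length(keep) == before) break
  }
  s <- paste(strsplit(seq, "")[[1]][keep], collapse = "")
  list(sequence = s, qualities = q[keep],
       dropped = nchar(s) < policy$min_length)
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# random read with blocky quality structure so trimming rules all trigger
random_read <- function(len = NULL) {
  if (is.null(len)) len <- sample(40:90, 1)
  n_blocks <- sample(1:4, 1)
  sizes <- diff(c(0, sort(sample(seq_len(len - 1), n_blocks - 1)), len))
  q <- unlist(lapply(sizes, function(s) {
    pmin(pmax(round(rnorm(s, mean = sample(c(2, 10, 18, 25, 35), 1), sd = 3)), 0), 41)
  }))
  list(sequence = random_seq(len), q = as.integer(q))
}
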