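# Standardization of MDA GC bias. The amplified metagenome over-represents
# low-GC sequence relative to the unamplified bulk sample; comparing the two
# GC distributions yields a per-GC-bin correction factor that is applied to
# mapped-read counts before computing relative abundances.

#' Weighted GC histogram
#'
#' Bins items (scaffolds or reads) by GC percentage into half-open bins
#' `[k, k + bin_width)` and normalizes the weight totals to fractions.
#' Weight by scaffold length or mapped reads depending on what the
#' distribution should represent.
#'
#' @param gc Numeric vector of GC fractions in `[0, 1]`.
#' @param weight Positive weights (default 1 per item: plain counts).
#' @param bin_width Bin width in GC percentage points (default 1).
#' @return A `gc_histogram` tibble (`gc_bin` lower edge in percent,
#'   `fraction`), fractions summing to 1.
#' @export
gc_histogram <- function(gc, weight = NULL, bin_width = 1) {
  if (length(gc) == 0) abort("cannot build a GC histogram from no items")
  if (any(gc < 0 | gc > 1)) abort("GC fractions must lie in [0, 1]")
  if (is.null(weight)) weight <- rep(1, length(gc))
  if (any(weight <= 0)) abort("weights must be positive")
  bin <- floor(gc * 100 / bin_width) * bin_width
  out <- tibble(gc_bin = bin, weight = weight) |>
    group_by(.data$gc_bin) |>
    summarise(fraction = sum(.data$weight), .groups = "drop") |>
    mutate(fraction = .data$fraction / sum(.data$fraction)) |>
    arrange(.data$gc_bin)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("gc_histogram", class(out))
  out
}

#' Per-GC-bin standardization factors from amplified vs bulk histograms
#'
#' For every bin occupied in both histograms the factor is
#' `bulk_fraction / amplified_fraction`; multiplying an amplified
#' observation by its bin factor recovers the share it would have had
#' without amplification bias. Bins occupied only in the amplified sample,
#' and bins whose occupancy falls below `min_fraction` in either histogram
#' (their ratio estimate would rest on a handful of observations), inherit
#' the factor of the nearest reliably occupied bin and are flagged as
#' smoothed.
#'
#' @param amplified,bulk [gc_histogram()]s with the same bin width.
#' @param min_fraction Minimum per-histogram bin occupancy for a direct
#'   ratio estimate (default 0.01); ignored if no common bin reaches it.
#' @return A `standardization_table` tibble (`gc_bin`, `factor`,
#'   `smoothed`), covering every bin occupied in the amplified sample.
#' @export
standardization_factors <- function(amplified, bulk, min_fraction = 0.01) {
  bw_a <- attr(amplified, "bin_width")
  bw_b <- attr(bulk, "bin_width")
  if (!isTRUE(all.equal(bw_a, bw_b))) abort("histograms have different bin widths")
  common <- intersect(amplified$gc_bin, bulk$gc_bin)
  if (length(common) == 0) abort("amplified and bulk histograms share no occupied GC bin")
  fa <- setNames(amplified$fraction, amplified$gc_bin)
  fb <- setNames(bulk$fraction, bulk$gc_bin)
  solid <- common[fa[as.character(common)] >= min_fraction &
                    fb[as.character(common)] >= min_fraction]
  if (length(solid) == 0) solid <- common
  exact <- tibble(
    gc_bin = sort(solid),
    factor = unname(fb[as.character(sort(solid))] / fa[as.character(sort(solid))]),
    smoothed = FALSE
  )
  only_a <- setdiff(amplified$gc_bin, solid)
  smoothed <- tibble(
    gc_bin = only_a,
    factor = vapply(only_a, function(b) {
      exact$factor[which.min(abs(exact$gc_bin - b))]
    }, numeric(1)),
    smoothed = TRUE
  )
  out <- bind_rows(exact, smoothed) |> arrange(.data$gc_bin)
  attr(out, "bin_width") <- bw_a
  class(out) <- c("standardization_table", class(out))
  out
}

# look up factors for GC fractions; smoothed fallback to nearest bin for
# values outside the table (e.g. a bin never seen during estimation)
factor_for_gc <- function(factors, gc) {
  bw <- attr(factors, "bin_width") %||% 1
  bin <- floor(gc * 100 / bw) * bw
  idx <- match(bin, factors$gc_bin)
  miss <- is.na(idx)
  if (any(miss)) {
    idx[miss] <- vapply(bin[miss], function(b) which.min(abs(factors$gc_bin - b)),
                        integer(1))
  }
  factors$factor[idx]
}

#' Standardized relative abundance of scaffold groups
#'
#' Corrects each scaffold's mapped-read count by its GC-bin standardization
#' factor and reports each group's share of the corrected total as a
#' percentage. Over a full partition of the scaffolds the abundances sum to
#' 100% (the output is a composition).
#'
#' @param scaffolds Tibble with columns `gc`, `mapped_reads`, and a grouping
#'   column (`bin_id` by default). All scaffolds of the assembly (or sample)
#'   must be present: the corrected total is the denominator.
#' @param factors A `standardization_table` (use NULL for raw abundances).
#' @param by Name of the grouping column (default "bin_id").
#' @return Tibble (`by` column, `abundance`), abundance in percent.
#' @export
standardized_abundance <- function(scaffolds, factors = NULL, by = "bin_id") {
  if (!all(c("gc", "mapped_reads", by) %in% names(scaffolds))) {
    abort(paste0("scaffold table needs columns gc, mapped_reads, ", by))
  }
  f <- if (is.null(factors)) rep(1, nrow(scaffolds)) else factor_for_gc(factors, scaffolds$gc)
  corrected <- scaffolds$mapped_reads * f
  denom <- sum(corrected)
  if (denom == 0) abort("corrected read total is zero")
  tibble(!!by := scaffolds[[by]], corrected = corrected) |>
    group_by(.data[[by]]) |>
    summarise(abundance = 100 * sum(.data$corrected) / denom, .groups = "drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
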