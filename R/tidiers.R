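# broom-style accessors for the package's fitted objects.

#' Tidy a bin set
#'
#' @param x A `bin_set`.
#' @param ... Unused.
#' @return The per-bin summary tibble (one row per bin).
#' @export
tidy.bin_set <- function(x, ...) x$bins

#' One-row summary of a bin set
#'
#' @param x A `bin_set`.
#' @param ... Unused.
#' @return Tibble: bin count, scaffold counts, binned length share, mean
#'   completeness, total duplicated markers.
#' @export
glance.bin_set <- function(x, ...) {
  tibble(
    n_bins = nrow(x$bins),
    n_scaffolds = nrow(x$members),
    n_unbinned = length(x$noise),
    total_length = sum(x$bins$total_length),
    mean_completeness = mean(x$bins$completeness),
    total_duplicated = sum(x$bins$duplicated),
    n_near_complete = sum(x$bins$quality != "partial")
  )
}

#' Tidy a sample clustering
#'
#' @param x A `sample_clustering`.
#' @param ... Unused.
#' @return The merge table (negative entries are leaves, positive earlier
#'   merges), with heights.
#' @export
tidy.sample_clustering <- function(x, ...) x$merges

#' One-row summary of a sample clustering
#'
#' @param x A `sample_clustering`.
#' @param ... Unused.
#' @return Tibble: sample count, metric, linkage, maximum merge height.
#' @export
glance.sample_clustering <- function(x, ...) {
  tibble(
    n_samples = length(x$sample_ids),
    metric = x$metric,
    linkage = x$linkage,
    max_height = max(x$merges$height)
  )
}
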