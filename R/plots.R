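# ggplot2 views of the pipeline's result objects.

#' Plot a bin set in pairwise log-coverage planes
#'
#' The 3D binning space shown as its three pairwise projections, points
#' colored by bin (noise in grey), sized by scaffold length when available.
#'
#' @param object A `bin_set`.
#' @param coverage Coverage tibble from [coverage_matrix()] for the three
#'   binning samples.
#' @param pseudocount Pseudocount for the log transform (default 0.01).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bin_set <- function(object, coverage, pseudocount = 0.01, ...) {
  samples <- setdiff(names(coverage), "scaffold_id")
  space <- coverage_space(coverage, pseudocount, allow_n = TRUE)
  pairs <- utils::combn(samples, 2, simplify = FALSE)
  dat <- purrr::map(pairs, function(p) {
    tibble(
      scaffold_id = rownames(space),
      x = space[, p[1]], y = space[, p[2]],
      panel = paste(p[1], "vs", p[2])
    )
  }) |>
    bind_rows() |>
    left_join(object$members, by = "scaffold_id") |>
    mutate(bin_id = dplyr::coalesce(.data$bin_id, "unbinned"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$bin_id)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_colour_viridis_d(end = 0.9, na.value = "grey70") +
    ggplot2::labs(x = "log10 coverage", y = "log10 coverage", colour = "bin") +
    ggplot2::theme_minimal()
}

#' Plot GC standardization factors
#'
#' @param object A `standardization_table`.
#' @param ... Unused.
#' @return A ggplot of log10 factor against GC bin; smoothed (borrowed)
#'   bins are hollow.
#' @export
autoplot.standardization_table <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$gc_bin, y = log10(.data$factor), shape = .data$smoothed)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = "GC bin (%)", y = "log10 standardization factor",
                  shape = "smoothed") +
    ggplot2::theme_minimal()
}

#' Plot a sample dendrogram
#'
#' @param object A `sample_clustering`.
#' @param ... Unused.
#' @return A ggplot dendrogram with sample labels.
#' @export
autoplot.sample_clustering <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  segs <- list()
  child_pos <- function(idx) {
    if (idx < 0) c(leaf_x[-idx], 0) else c(node_x[idx], node_h[idx])
  }
  for (k in seq_len(nrow(hc$merge))) {
    a <- child_pos(hc$merge[k, 1])
    b <- child_pos(hc$merge[k, 2])
    node_x[k] <- (a[1] + b[1]) / 2
    segs[[length(segs) + 1]] <- tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], hc$height[k]), yend = c(hc$height[k], hc$height[k], hc$height[k])
    )
  }
  labdat <- tibble(x = leaf_x, y = 0, label = hc$labels)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = bind_rows(segs),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)
    ) +
    ggplot2::geom_text(
      data = labdat,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      angle = 90, hjust = 1.1, size = 3
    ) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(x = NULL, y = sprintf("%s distance (%s linkage)",
                                        object$metric, object$linkage)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}
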