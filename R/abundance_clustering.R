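# Replicate-similarity analysis: hierarchical clustering of per-sample
# genus-level abundance profiles. Colonies of the same species share a
# community composition, so replicates should appear as sister leaves.

#' Keep genera with differential cross-sample abundance
#'
#' Genera whose max-min abundance range across samples falls below
#' `min_range` carry no grouping signal and are dropped.
#'
#' @param table Tibble: `sample_id` plus one relative-abundance column per
#'   genus (rows are renormalized to sum to 1).
#' @param min_range Minimum cross-sample abundance range (default 0.001).
#' @return The reduced table (same rows, surviving genus columns).
#' @export
select_differential_genera <- function(table, min_range = 0.001) {
  if (nrow(table) < 2) abort("need at least 2 samples")
  m <- normalize_profiles(table)
  rng <- apply(m, 2, function(v) max(v) - min(v))
  keep <- colnames(m)[rng >= min_range]
  dplyr::bind_cols(table["sample_id"], as_tibble(m[, keep, drop = FALSE]))
}

normalize_profiles <- function(table) {
  m <- as.matrix(table[, setdiff(names(table), "sample_id"), drop = FALSE])
  if (any(m < 0)) abort("abundances must be non-negative")
  rs <- rowSums(m)
  if (any(rs == 0)) abort("a sample has an all-zero profile")
  rownames(m) <- table$sample_id
  sweep(m, 1, rs, "/")
}

#' Hierarchically cluster samples by abundance profile
#'
#' Average-linkage agglomerative clustering of the samples, on Euclidean or
#' Bray-Curtis distance between relative-abundance profiles. Samples are
#' ordered lexicographically before clustering so merge tie-breaking is
#' deterministic.
#'
#' @param table Tibble: `sample_id` plus genus abundance columns.
#' @param metric "euclidean" or "bray" (Bray-Curtis).
#' @param linkage Agglomeration method (default "average").
#' @return A `sample_clustering` object wrapping the `hclust` tree, its
#'   `ape::phylo` form, and a merge-height table.
#' @export
cluster_samples <- function(table, metric = c("euclidean", "bray"),
                            linkage = "average") {
  metric <- match.arg(metric)
  if (nrow(table) < 2) abort("need at least 2 samples")
  m <- normalize_profiles(table)
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- if (metric == "euclidean") dist(m) else vegan::vegdist(m, method = "bray")
  hc <- hclust(d, method = linkage)
  merges <- tibble(
    step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height = hc$height
  )
  structure(
    list(hclust = hc, phylo = ape::as.phylo(hc), merges = merges,
         metric = metric, linkage = linkage, sample_ids = rownames(m)),
    class = "sample_clustering"
  )
}

#' Are two samples sister leaves of the clustering?
#'
#' @param clustering A `sample_clustering`.
#' @param a,b Sample IDs.
#' @return TRUE when `a` and `b` merge directly (form a cherry).
#' @export
is_sister_pair <- function(clustering, a, b) {
  hc <- clustering$hclust
  ia <- match(a, hc$labels)
  ib <- match(b, hc$labels)
  if (is.na(ia) || is.na(ib)) abort("unknown sample ID")
  any(apply(hc$merge, 1, function(r) setequal(r, c(-ia, -ib))))
}

#' Write a sample clustering as a newick tree
#'
#' Branch lengths derive from the merge heights.
#'
#' @param clustering A `sample_clustering`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clustering, path) {
  ape::write.tree(clustering$phylo, file = path)
  invisible(path)
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("<sample_clustering> %d samples, %s distance, %s linkage\n",
              length(x$sample_ids), x$metric, x$linkage))
  print(x$merges)
  invisible(x)
}
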