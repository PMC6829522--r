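# Differential-coverage binning. Scaffolds of one population share an
# abundance profile across colony samples, so in the 3D space of
# log-coverage they form a tight cloud; density clustering replaces the
# interactive 3D selection a human would do, with documented, deterministic
# parameters. Mixed clusters (populations with coincidentally similar
# abundance profiles) are split by tetranucleotide composition and GC.

#' Log-coverage binning space
#'
#' Element-wise `log10(depth + pseudocount)` over the three binning
#' samples. The pseudocount keeps zero-coverage scaffolds finite: zero
#' depth is common for colony-specific populations.
#'
#' @param coverage Tibble from [coverage_matrix()]: `scaffold_id` plus one
#'   depth column per sample.
#' @param pseudocount Depth added before the log (default 0.01).
#' @param allow_n Permit other than 3 samples (the binning space of the
#'   method is 3D; generalizations are the caller's responsibility).
#' @return Numeric matrix (scaffolds x samples), rows named by scaffold.
#' @export
coverage_space <- function(coverage, pseudocount = 0.01, allow_n = FALSE) {
  m <- as.matrix(coverage[, setdiff(names(coverage), "scaffold_id"), drop = FALSE])
  if (ncol(m) != 3 && !allow_n) {
    abort("binning space expects exactly 3 samples (set allow_n = TRUE to override)")
  }
  if (any(m < 0)) abort("depths must be non-negative")
  out <- log10(m + pseudocount)
  rownames(out) <- coverage$scaffold_id
  out
}

#' Density-based clustering of scaffolds in log-coverage space
#'
#' DBSCAN with Euclidean distance: a point with at least `min_cluster_size`
#' neighbors (total neighbor weight, excluding itself) within
#' `neighborhood_radius` is a core point; clusters are the connected
#' components of core points plus the border points they reach; everything
#' else is noise (label 0). Labels are deterministic given input order.
#'
#' @param points Numeric matrix (scaffolds x coordinates), e.g. from
#'   [coverage_space()].
#' @param min_cluster_size Core-point neighbor threshold (default 10).
#' @param neighborhood_radius Neighborhood radius in log10-coverage units
#'   (default 0.3).
#' @param length_weights Optional per-scaffold weights (e.g. lengths scaled
#'   to a typical scaffold) counted instead of 1 per neighbor.
#' @return Integer label vector (0 = noise), named by scaffold when
#'   `points` has row names.
#' @export
cluster_scaffolds <- function(points, min_cluster_size = 10,
                              neighborhood_radius = 0.3,
                              length_weights = NULL) {
  if (neighborhood_radius <= 0) abort("neighborhood_radius must be positive")
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) abort("no points to cluster")
  w <- length_weights %||% rep(1, n)
  dm <- as.matrix(dist(points))
  nb <- lapply(seq_len(n), function(i) which(dm[i, ] <= neighborhood_radius & seq_len(n) != i))
  core <- vapply(seq_len(n), function(i) sum(w[nb[[i]]]) >= min_cluster_size, logical(1))

  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  names(labels) <- rownames(points)
  labels
}

# duplicated-marker count of a scaffold set
duplicated_markers <- function(ids, marker_hits, catalog_size = 107) {
  bin_completeness(marker_hits[marker_hits$scaffold_id %in% ids, ], catalog_size)$duplicated
}

#' Composition-based refinement of a mixed bin
#'
#' A bin whose duplicated-marker count exceeds `max_duplicated` is taken to
#' mix populations. Its member scaffolds are projected onto the first two
#' principal components of a length-weighted PCA of their tetranucleotide-
#' frequency matrix (long scaffolds carry low-noise composition estimates,
#' so they anchor the axes; GC content is a linear combination of the TNF
#' features and is therefore already represented in this space), and the
#' bin is split by length-weighted 2-means seeded from the two mutually
#' most distant members (a deterministic initialization). A split is
#' accepted only when it reduces the total duplicated-marker count;
#' accepted sub-bins are refined recursively. Should the TNF matrix be
#' degenerate (no varying 4-mer), the per-scaffold GC is used as the sole
#' axis.
#'
#' @param bin_scaffolds Character vector of member scaffold IDs (>= 2).
#' @param gc Named numeric vector of per-scaffold GC fractions (degenerate-
#'   TNF fallback axis).
#' @param tnf Numeric matrix of per-scaffold TNF vectors, rows named by
#'   scaffold.
#' @param marker_hits Marker hit tibble (whole assembly; filtered per bin).
#' @param lengths Optional named scaffold lengths used as weights (default:
#'   equal weights).
#' @param max_duplicated Duplication threshold that triggers refinement
#'   (default 5).
#' @param catalog_size Marker catalog size for the accounting.
#' @return A list of character vectors: the refined sub-bins (a list of
#'   length 1 when the bin is returned unchanged).
#' @export
refine_bin <- function(bin_scaffolds, gc, tnf, marker_hits, lengths = NULL,
                       max_duplicated = 5, catalog_size = 107) {
  dup <- duplicated_markers(bin_scaffolds, marker_hits, catalog_size)
  if (length(bin_scaffolds) < 2 || dup <= max_duplicated) {
    return(list(bin_scaffolds))
  }
  w <- if (is.null(lengths)) {
    setNames(rep(1, length(bin_scaffolds)), bin_scaffolds)
  } else {
    lengths[bin_scaffolds]
  }
  axes <- refinement_axes(bin_scaffolds, gc, tnf, w)
  if (is.null(axes)) return(list(bin_scaffolds))
  cl <- weighted_kmeans2(axes, w)
  if (is.null(cl)) return(list(bin_scaffolds))
  sub <- split(bin_scaffolds, cl)
  if (length(sub) < 2) return(list(bin_scaffolds))
  new_dup <- sum(vapply(sub, duplicated_markers, numeric(1),
                        marker_hits = marker_hits, catalog_size = catalog_size))
  if (new_dup >= dup) return(list(bin_scaffolds))
  unlist(
    lapply(sub, refine_bin, gc = gc, tnf = tnf, marker_hits = marker_hits,
           lengths = lengths, max_duplicated = max_duplicated,
           catalog_size = catalog_size),
    recursive = FALSE, use.names = FALSE
  )
}

# first two PCs of a length-weighted PCA of the bin's TNF; GC fallback for
# degenerate composition; NULL when nothing varies
refinement_axes <- function(ids, gc, tnf, w) {
  x <- tnf[ids, , drop = FALSE]
  keep <- which(apply(x, 2, sd) > 0)
  if (length(keep) < 2) {
    g <- gc[ids]
    if (sd(g) == 0) return(NULL)
    return(matrix(g, ncol = 1, dimnames = list(ids, "gc")))
  }
  cw <- stats::cov.wt(x[, keep, drop = FALSE], wt = w / sum(w), method = "ML")
  ev <- eigen(cw$cov, symmetric = TRUE)
  npc <- min(2, ncol(ev$vectors))
  sweep(x[, keep, drop = FALSE], 2, cw$center) %*% ev$vectors[, seq_len(npc), drop = FALSE]
}

# deterministic weighted 2-means: farthest-pair initialization, Lloyd
# iterations with weighted centroids; NULL on degenerate input
weighted_kmeans2 <- function(axes, w, max_iter = 100) {
  dm <- as.matrix(dist(axes))
  far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  centers <- axes[far, , drop = FALSE]
  if (all(centers[1, ] == centers[2, ])) return(NULL)
  cl <- integer(nrow(axes))
  for (it in seq_len(max_iter)) {
    d1 <- rowSums(sweep(axes, 2, centers[1, ])^2)
    d2 <- rowSums(sweep(axes, 2, centers[2, ])^2)
    cl <- ifelse(d1 <= d2, 1L, 2L)
    if (length(unique(cl)) < 2) return(NULL)
    new <- rbind(
      colSums(axes * w * (cl == 1L)) / sum(w[cl == 1L]),
      colSums(axes * w * (cl == 2L)) / sum(w[cl == 2L])
    )
    if (all(abs(new - centers) < 1e-12)) break
    centers <- new
  }
  cl
}

#' Apply refinement to every clustered bin
#'
#' @param labels Integer labels from [cluster_scaffolds()] (0 = noise),
#'   named by scaffold.
#' @param gc,tnf,marker_hits,lengths,max_duplicated,catalog_size As
#'   [refine_bin()].
#' @return Membership tibble (`scaffold_id`, `bin_id`), noise scaffolds
#'   labeled `"unbinned"`; refined sub-bins get suffixed IDs.
#' @export
refine_bins <- function(labels, gc, tnf, marker_hits, lengths = NULL,
                        max_duplicated = 5, catalog_size = 107) {
  out <- list(tibble(scaffold_id = names(labels)[labels == 0L],
                     bin_id = rep("unbinned", sum(labels == 0L))))
  for (cl in sort(unique(labels[labels > 0L]))) {
    ids <- names(labels)[labels == cl]
    sub <- refine_bin(ids, gc, tnf, marker_hits, lengths, max_duplicated,
                      catalog_size)
    bid <- if (length(sub) == 1) {
      sprintf("bin_%02d", cl)
    } else {
      sprintf("bin_%02d%s", cl, letters[seq_along(sub)])
    }
    out[[length(out) + 1]] <- tibble(
      scaffold_id = unlist(sub, use.names = FALSE),
      bin_id = rep(bid, lengths(sub))
    )
  }
  bind_rows(out) |> arrange(.data$scaffold_id)
}

#' Assemble genome bins with summary statistics
#'
#' Builds the per-bin accounting a draft-genome table reports: contig
#' count, total length, length-weighted GC, marker completeness and
#' duplication, quality flag, and (when mapped-read counts are given)
#' standardized relative abundance per sample and overall.
#'
#' @param membership Tibble (`scaffold_id`, `bin_id`) covering all
#'   scaffolds; noise rows carry `bin_id = "unbinned"`.
#' @param profiles Profile tibble from [scaffold_profiles()] (`scaffold_id`,
#'   `length`, `gc`).
#' @param marker_hits Marker hit tibble.
#' @param catalog_size Marker catalog size (default 107).
#' @param mapped_reads Optional tibble (`scaffold_id`, `sample_id`,
#'   `mapped_reads`).
#' @param factors Optional `standardization_table` for abundance
#'   standardization.
#' @return A `bin_set` object: `bins` (summary tibble), `members`
#'   (membership), `noise` (unbinned scaffold IDs), `abundance` (long
#'   per-sample tibble, when reads given).
#' @export
assemble_bins <- function(membership, profiles, marker_hits,
                          catalog_size = 107, mapped_reads = NULL,
                          factors = NULL) {
  if (!setequal(membership$scaffold_id, profiles$scaffold_id)) {
    abort("membership must cover exactly the profiled scaffolds")
  }
  dat <- left_join(membership, profiles, by = "scaffold_id")
  hit_bin <- left_join(marker_hits, membership, by = "scaffold_id")

  bins <- dat |>
    filter(.data$bin_id != "unbinned") |>
    group_by(.data$bin_id) |>
    summarise(
      n_contigs = dplyr::n(),
      total_length = sum(.data$length),
      gc = sum(.data$gc * .data$length) / sum(.data$length),
      .groups = "drop"
    )
  qual <- bins$bin_id |>
    purrr::map(function(b) {
      bin_completeness(hit_bin[which(hit_bin$bin_id == b), ], catalog_size)
    }) |>
    bind_rows()
  bins <- dplyr::bind_cols(bins, qual) |>
    mutate(quality = quality_flag(.data$completeness, .data$duplicated))

  abundance <- NULL
  if (!is.null(mapped_reads)) {
    ab_tbl <- mapped_reads |>
      left_join(membership, by = "scaffold_id") |>
      left_join(profiles[, c("scaffold_id", "gc")], by = "scaffold_id")
    per_sample <- ab_tbl |>
      split(ab_tbl$sample_id) |>
      purrr::imap(function(x, s) {
        standardized_abundance(x, factors, by = "bin_id") |>
          mutate(sample_id = s)
      }) |>
      bind_rows()
    overall <- ab_tbl |>
      group_by(.data$scaffold_id, .data$bin_id, .data$gc) |>
      summarise(mapped_reads = sum(.data$mapped_reads), .groups = "drop") |>
      standardized_abundance(factors, by = "bin_id") |>
      mutate(sample_id = "overall")
    abundance <- bind_rows(per_sample, overall)
    wide <- abundance |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "abundance",
                         names_prefix = "abundance_", values_fill = 0)
    bins <- left_join(bins, wide, by = "bin_id") |>
      mutate(dplyr::across(dplyr::starts_with("abundance_"),
                           \(v) dplyr::coalesce(v, 0)))
  }

  structure(
    list(
      bins = bins,
      members = membership,
      noise = membership$scaffold_id[membership$bin_id == "unbinned"],
      abundance = abundance,
      catalog_size = catalog_size
    ),
    class = "bin_set"
  )
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("<bin_set> %d bins over %d scaffolds (%d unbinned)\n",
              nrow(x$bins), nrow(x$members), length(x$noise)))
  print(x$bins)
  invisible(x)
}

#' Extract the read pairs associated with a bin
#'
#' A pair is selected when at least one mate has a primary alignment to a
#' bin scaffold; both mates of a selected pair are meant for downstream
#' re-assembly (running the assembler is an external hook).
#'
#' @param alignments Alignment tibble with `read_id`, `scaffold_id`, `mate`
#'   (and optionally `sample_id`).
#' @param bin_scaffolds Character vector of the bin's scaffold IDs.
#' @return Tibble of selected pair IDs (`sample_id` if present, `read_id`),
#'   sorted.
#' @export
extract_bin_reads <- function(alignments, bin_scaffolds) {
  if (!"mate" %in% names(alignments)) abort("alignments must carry a mate flag")
  sel <- alignments[alignments$scaffold_id %in% bin_scaffolds, ]
  cols <- intersect(c("sample_id", "read_id"), names(alignments))
  distinct(sel[, cols, drop = FALSE]) |> arrange(dplyr::across(dplyr::all_of(cols)))
}

#' Evaluate recovered bins against planted truth
#'
#' Length-weighted per-genome recall (share of the genome's scaffold length
#' landing in its majority bin) and precision (share of that bin's length
#' coming from the genome).
#'
#' @param bin_set A `bin_set` (or a membership tibble).
#' @param truth Tibble (`scaffold_id`, `genome_id`).
#' @param lengths Tibble (`scaffold_id`, `length`).
#' @return Tibble (`genome_id`, `bin_id`, `recall`, `precision`).
#' @export
evaluate_bins <- function(bin_set, truth, lengths) {
  members <- if (inherits(bin_set, "bin_set")) bin_set$members else bin_set
  dat <- truth |>
    left_join(members, by = "scaffold_id") |>
    left_join(lengths, by = "scaffold_id") |>
    mutate(bin_id = dplyr::coalesce(.data$bin_id, "unbinned"))
  cell <- dat |>
    group_by(.data$genome_id, .data$bin_id) |>
    summarise(length = sum(.data$length), .groups = "drop")
  bin_tot <- cell |>
    group_by(.data$bin_id) |>
    summarise(bin_length = sum(.data$length), .groups = "drop")
  gen_tot <- cell |>
    group_by(.data$genome_id) |>
    summarise(genome_length = sum(.data$length), .groups = "drop")
  cell |>
    filter(.data$bin_id != "unbinned") |>
    left_join(gen_tot, by = "genome_id") |>
    left_join(bin_tot, by = "bin_id") |>
    group_by(.data$genome_id) |>
    slice(which.max(.data$length)) |>
    ungroup() |>
    mutate(recall = .data$length / .data$genome_length,
           precision = .data$length / .data$bin_length) |>
    select("genome_id", "bin_id", "recall", "precision")
}
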