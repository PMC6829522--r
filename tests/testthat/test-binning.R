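test_that("the log-coverage transform is finite, anchored and monotone", {
  cov <- tibble::tibble(scaffold_id = c("a", "b"), s1 = c(0, 0.99),
                        s2 = c(1, 2), s3 = c(3, 4))
  sp <- coverage_space(cov)
  expect_equal(sp["a", "s1"], -2)
  expect_equal(sp["b", "s1"], 0)
  expect_true(all(is.finite(sp)))
  # strictly monotone per coordinate
  d <- sort(runif(20, 0, 100))
  expect_true(all(diff(log10(d + 0.01)) > 0))
  expect_error(coverage_space(cov[, 1:3]), "3 samples")
  expect_silent(coverage_space(cov[, 1:3], allow_n = TRUE))
})

test_that("density clustering recovers well-separated clouds and flags noise", {
  set.seed(701)
  n <- 200
  cloud <- function(center) {
    matrix(rnorm(3 * n, sd = 0.1), ncol = 3) +
      matrix(center, n, 3, byrow = TRUE)
  }
  pts <- rbind(cloud(c(0, 0, 0)), cloud(c(2, 0, 0)))
  rownames(pts) <- sprintf("p%03d", seq_len(2 * n))
  labels <- cluster_scaffolds(pts, min_cluster_size = 10,
                              neighborhood_radius = 0.3)
  expect_equal(sort(unique(labels[labels > 0])), c(1, 2))
  truth <- rep(1:2, each = n)
  assigned <- labels > 0
  expect_true(all(labels[assigned] == truth[assigned]))
  expect_equal(sum(assigned), 2 * n) # full concordance at this separation

  # single point below the core threshold is noise
  expect_equal(unname(cluster_scaffolds(matrix(0, 1, 3), min_cluster_size = 5)), 0L)

  # a pile of identical points is one cluster
  same <- matrix(1, 20, 3)
  expect_equal(unique(cluster_scaffolds(same, min_cluster_size = 5)), 1L)

  expect_error(cluster_scaffolds(pts, neighborhood_radius = 0), "positive")

  # determinism
  expect_identical(labels, cluster_scaffolds(pts, 10, 0.3))
})

test_that("length weights let few heavy scaffolds form a core", {
  pts <- matrix(rnorm(9, sd = 0.01), 3, 3)
  # 3 points, weights 5 each: neighbor weight 10 >= threshold
  lab_w <- cluster_scaffolds(pts, min_cluster_size = 10,
                             neighborhood_radius = 0.5,
                             length_weights = c(5, 5, 5))
  expect_equal(unique(lab_w), 1L)
  lab_u <- cluster_scaffolds(pts, min_cluster_size = 10,
                             neighborhood_radius = 0.5)
  expect_equal(unique(lab_u), 0L)
})

test_that("refinement splits a mixed high-GC bin and leaves clean bins alone", {
  catalog <- tiny_catalog(40, seed = 31)
  genomes <- high_gc_pair(seed = 32, catalog = catalog)
  sc <- fragment_to_scaffolds(genomes, min_len = 1000, mean_len = 4000, seed = 33)
  hits <- detect_markers(sc$scaffolds, catalog)
  tnf <- compute_tnf(setNames(sc$scaffolds$sequence, sc$scaffolds$scaffold_id))
  gc <- setNames(compute_gc(sc$scaffolds$sequence), sc$scaffolds$scaffold_id)
  lens <- setNames(sc$scaffolds$length, sc$scaffolds$scaffold_id)

  # clean bin: no duplicated markers, returned unchanged
  clean <- sc$truth$scaffold_id[sc$truth$genome_id == "hgA"]
  out <- refine_bin(clean, gc, tnf, hits, lens, catalog_size = 40)
  expect_equal(out, list(clean))

  # merged two-genome bin: split into sub-bins with few duplicates
  merged <- sc$scaffolds$scaffold_id
  out2 <- refine_bin(merged, gc, tnf, hits, lens, catalog_size = 40)
  expect_equal(length(out2), 2)
  for (sub in out2) {
    expect_lte(duplicated_markers_for_test(sub, hits, 40), 1)
    # each sub-bin is dominated by one genome (length-weighted purity)
    src <- sc$truth$genome_id[match(sub, sc$truth$scaffold_id)]
    purity <- max(tapply(lens[sub], src, sum)) / sum(lens[sub])
    expect_gte(purity, 0.95)
  }

  # a split that cannot reduce duplicates is rejected: every scaffold of a
  # clean genome carries the same marker twice via a doctored hit table
  fake_hits <- tibble::tibble(scaffold_id = clean, marker_id = "scg001",
                              count = 2L)
  out3 <- refine_bin(clean, gc, tnf, fake_hits, lens, max_duplicated = 0,
                     catalog_size = 40)
  expect_equal(out3, list(clean))
})

test_that("assembled bins carry conservation-checked statistics", {
  prof <- tibble::tibble(
    scaffold_id = c("a", "b", "c", "d"),
    length = c(1000L, 2000L, 3000L, 1500L),
    gc = c(0.4, 0.5, 0.6, 0.3)
  )
  membership <- tibble::tibble(
    scaffold_id = c("a", "b", "c", "d"),
    bin_id = c("bin_01", "bin_01", "bin_01", "unbinned")
  )
  hits <- tibble::tibble(scaffold_id = c("a", "a", "b"),
                         marker_id = c("m1", "m2", "m1"), count = c(1L, 1L, 1L))
  bs <- assemble_bins(membership, prof, hits, catalog_size = 10)
  expect_equal(bs$bins$total_length, 6000L)
  expect_equal(bs$bins$n_contigs, 3L)
  # length-weighted GC against hand computation
  expect_equal(bs$bins$gc, (0.4 * 1000 + 0.5 * 2000 + 0.6 * 3000) / 6000)
  expect_equal(bs$bins$found, 2L)
  expect_equal(bs$bins$duplicated, 1L)
  expect_equal(bs$noise, "d")
  # bins plus noise partition the scaffolds
  expect_setequal(bs$members$scaffold_id, prof$scaffold_id)

  # abundance columns appear when read counts are supplied
  reads <- tibble::tibble(
    scaffold_id = c("a", "b", "c", "d"),
    sample_id = "s1",
    mapped_reads = c(10, 10, 10, 30)
  )
  bs2 <- assemble_bins(membership, prof, hits, 10, mapped_reads = reads)
  expect_equal(bs2$bins$abundance_s1, 50)
  expect_equal(bs2$bins$abundance_overall, 50)

  expect_error(assemble_bins(membership[1:2, ], prof, hits), "cover")

  # tidy/glance accessors
  expect_equal(nrow(tidy(bs)), 1)
  expect_equal(glance(bs)$n_bins, 1)
  expect_equal(glance(bs)$n_unbinned, 1)
})

test_that("bin read extraction selects exactly pairs with a mate on the bin", {
  set.seed(702)
  scaffolds <- sprintf("s%02d", 1:6)
  bin <- scaffolds[1:2]
  n <- 300
  aln <- tibble::tibble(
    read_id = rep(sprintf("r%03d", seq_len(n)), each = 2),
    mate = rep(1:2, n),
    scaffold_id = sample(c(scaffolds, NA), 2 * n, replace = TRUE)
  )
  aln <- aln[!is.na(aln$scaffold_id), ]
  got <- extract_bin_reads(aln, bin)$read_id
  want <- sort(unique(aln$read_id[aln$scaffold_id %in% bin]))
  expect_identical(got, want)
  # both-mates-on-bin and one-mate-on-bin are included, neither-mate excluded
  expect_true(all(got %in% aln$read_id))
  expect_error(extract_bin_reads(aln[, c("read_id", "scaffold_id")], bin),
               "mate")
})

test_that("bin evaluation computes length-weighted precision and recall", {
  truth <- tibble::tibble(scaffold_id = c("a", "b", "c", "d"),
                          genome_id = c("g1", "g1", "g2", "g2"))
  lengths <- tibble::tibble(scaffold_id = c("a", "b", "c", "d"),
                            length = c(1000, 1000, 1000, 1000))
  # perfect binning
  perfect <- tibble::tibble(scaffold_id = c("a", "b", "c", "d"),
                            bin_id = c("x", "x", "y", "y"))
  ev <- evaluate_bins(perfect, truth, lengths)
  expect_equal(ev$recall, c(1, 1))
  expect_equal(ev$precision, c(1, 1))
  # everything in one bin over two equal genomes: precision 0.5
  merged <- tibble::tibble(scaffold_id = c("a", "b", "c", "d"), bin_id = "x")
  ev2 <- evaluate_bins(merged, truth, lengths)
  expect_equal(ev2$precision, c(0.5, 0.5))
  expect_equal(ev2$recall, c(1, 1))
})
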