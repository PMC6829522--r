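test_that("generated genomes honor GC targets, marker placement and determinism", {
  catalog <- tiny_catalog(120, seed = 3)

  # zero-GC limit: only A/T
  g0 <- generate_genome("at", 10000, 0, 0, seed = 1)
  expect_true(grepl("^[AT]+$", g0$sequence))

  # realized GC close to target with many planted markers, all findable
  g <- generate_genome("hi", 200000, 0.68, 105, catalog, seed = 2)
  expect_gte(g$gc, 0.67)
  expect_lte(g$gc, 0.69)
  mk <- g$markers[[1]]
  expect_equal(nrow(mk), 105)
  expect_true(all(mk$start >= 0 & mk$end <= g$length))
  # non-overlapping intervals
  expect_true(all(mk$start[-1] >= head(mk$end, -1) - 0L |
                    !is.unsorted(mk$start)))
  ord <- order(mk$start)
  expect_true(all(mk$start[ord][-1] >= mk$end[ord][-nrow(mk)]))
  tags <- catalog$sequence[match(mk$marker_id, catalog$marker_id)]
  found <- vapply(seq_len(nrow(mk)), function(i) {
    substr(g$sequence, mk$start[i] + 1, mk$end[i]) == tags[i]
  }, logical(1))
  expect_true(all(found))
  # every marker findable by exact substring search
  expect_true(all(vapply(tags, function(t) grepl(t, g$sequence, fixed = TRUE),
                         logical(1))))

  # determinism
  g_again <- generate_genome("hi", 200000, 0.68, 105, catalog, seed = 2)
  expect_identical(g$sequence, g_again$sequence)
  expect_identical(g$markers, g_again$markers)

  # genome-specific composition: same GC, different skew, distinct TNF
  a <- generate_genome("a", 50000, 0.68, 0, seed = 5, gc_skew = 0.5)
  b <- generate_genome("b", 50000, 0.68, 0, seed = 6, gc_skew = 0.65)
  d_same <- sqrt(sum((compute_tnf(a$sequence) -
                        compute_tnf(generate_genome("a2", 50000, 0.68, 0, seed = 7,
                                                    gc_skew = 0.5)$sequence))^2))
  d_diff <- sqrt(sum((compute_tnf(a$sequence) - compute_tnf(b$sequence))^2))
  expect_gt(d_diff, 3 * d_same)

  expect_error(generate_genome("x", 5000, 0.5), "10 kbp")
  expect_error(generate_genome("x", 10000, 1.5), "target_gc")
  expect_error(generate_genome("x", 10000, 0.5, 200, tiny_catalog(20)), "catalog")
})

test_that("abundance designs normalize columns and flag flat communities", {
  m <- matrix(c(8, 2, 1, 9), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  d <- abundance_design(m)
  expect_equal(colSums(d$matrix), c(s1 = 1, s2 = 1))
  expect_warning(abundance_design(matrix(c(1, 1, 1, 1), 2)), "ratio")
  expect_error(abundance_design(matrix(c(1, 1, 0, 0), 2)), "all-zero")
  expect_error(abundance_design(matrix(c(-1, 2, 1, 1), 2)), "non-negative")
})

test_that("MDA bias weights are uniform at beta 0 and strictly decreasing in GC", {
  gc <- seq(0, 1, by = 0.05)
  expect_equal(bias_weight(mda_bias_model(0), gc), rep(1, length(gc)))
  w <- bias_weight(mda_bias_model(2), gc)
  expect_true(all(diff(w) < 0))
  expect_error(mda_bias_model(-1), "non-negative")
})

test_that("unbiased read simulation splits pairs binomially between genomes", {
  genomes <- low_high_pair()
  d <- even_design(genomes)
  n <- 10000
  rd <- simulate_colony_reads(genomes, d, n_pairs = n, read_len = 100,
                              insert_mean = 300, insert_sd = 30,
                              error_rate = 0, seed = 9)
  counts <- table(rd$truth$genome_id)
  # 3 binomial standard deviations around n/2
  sd3 <- 3 * sqrt(n * 0.25)
  expect_true(all(abs(counts - n / 2) <= sd3))
  # conservation: one truth entry per pair
  expect_equal(nrow(rd$truth), n)
  expect_false(anyDuplicated(rd$truth$read_id) > 0)
})

test_that("MDA bias shifts reads toward the low-GC genome, reproducibly across seeds", {
  genomes <- low_high_pair()
  d <- even_design(genomes)
  for (s in 1:5) {
    rd <- simulate_colony_reads(genomes, d, n_pairs = 10000, read_len = 100,
                                insert_mean = 300, insert_sd = 30,
                                error_rate = 0, bias = mda_bias_model(3),
                                seed = s)
    counts <- table(rd$truth$genome_id)
    expect_gt(counts[["lo"]], counts[["hi"]])
  }
})

test_that("error-free reads are exact (or reverse-complement) genome substrings", {
  genomes <- low_high_pair()
  rd <- simulate_colony_reads(genomes, even_design(genomes), n_pairs = 50,
                              read_len = 80, insert_mean = 250, insert_sd = 20,
                              error_rate = 0, seed = 4)
  r <- rd$reads$s1
  gseq <- setNames(genomes$sequence, genomes$genome_id)
  src <- gseq[rd$truth$genome_id]
  expect_true(all(vapply(seq_len(nrow(r)), function(i) {
    grepl(r$sequence1[i], src[i], fixed = TRUE) &&
      grepl(revcomp(r$sequence2[i]), src[i], fixed = TRUE)
  }, logical(1))))
  # with errors, qualities stay aligned and Phred+33 encoded
  rd2 <- simulate_colony_reads(genomes, even_design(genomes), n_pairs = 20,
                               read_len = 80, insert_mean = 250,
                               insert_sd = 20, error_rate = 0.01, seed = 4)
  expect_true(all(nchar(rd2$reads$s1$quality1) == 80))
})

test_that("bulk simulation equals a beta-0 colony run and has higher mean GC than a biased one", {
  genomes <- low_high_pair()
  w <- c(lo = 0.5, hi = 0.5)
  bulk <- simulate_bulk_reads(genomes, w, n_pairs = 2000, sample_id = "s1",
                              read_len = 100, insert_mean = 300,
                              insert_sd = 30, error_rate = 0, seed = 21)
  colony <- simulate_colony_reads(genomes, even_design(genomes),
                                  n_pairs = 2000, read_len = 100,
                                  insert_mean = 300, insert_sd = 30,
                                  error_rate = 0, bias = mda_bias_model(0),
                                  seed = 21)
  expect_identical(bulk$reads$s1, colony$reads$s1)
  expect_identical(bulk$truth, colony$truth)

  for (s in 1:5) {
    bk <- simulate_bulk_reads(genomes, w, n_pairs = 4000, read_len = 100,
                              insert_mean = 300, insert_sd = 30,
                              error_rate = 0, seed = 30 + s)
    bi <- simulate_colony_reads(genomes, even_design(genomes), n_pairs = 4000,
                                read_len = 100, insert_mean = 300,
                                insert_sd = 30, error_rate = 0,
                                bias = mda_bias_model(3), seed = 30 + s)
    expect_gt(mean(gc_of_reads(bk)), mean(gc_of_reads(bi)))
  }
})

test_that("mean read GC is non-increasing in bias strength", {
  genomes <- low_high_pair()
  d <- even_design(genomes)
  for (s in 1:5) {
    gcs <- vapply(c(0, 1, 3), function(beta) {
      rd <- simulate_colony_reads(genomes, d, n_pairs = 3000, read_len = 100,
                                  insert_mean = 300, insert_sd = 30,
                                  error_rate = 0, bias = mda_bias_model(beta),
                                  seed = 50 + s)
      mean(gc_of_reads(rd))
    }, numeric(1))
    expect_true(all(diff(gcs) <= 0))
  }
})

test_that("fragmentation conserves genome length and honors the length floor", {
  genomes <- low_high_pair()
  sc <- fragment_to_scaffolds(genomes, min_len = 1000, mean_len = 3000, seed = 2)
  expect_true(all(sc$scaffolds$length >= 1000))
  expect_true(all(nchar(sc$scaffolds$sequence) == sc$scaffolds$length))
  # conservation: emitted + discarded pieces cover each genome exactly
  per_genome <- tapply(sc$pieces$length, sc$pieces$genome_id, sum)
  expect_equal(unname(as.numeric(per_genome[genomes$genome_id])),
               as.numeric(genomes$length))
  # determinism
  sc2 <- fragment_to_scaffolds(genomes, min_len = 1000, mean_len = 3000, seed = 2)
  expect_identical(sc$scaffolds, sc2$scaffolds)
  expect_error(fragment_to_scaffolds(genomes, min_len = 2000, mean_len = 1500),
               "mean_len")
  expect_error(fragment_to_scaffolds(genomes, min_len = 500), "1 kbp")

  # marker intervals are never split by default
  catalog <- tiny_catalog(40)
  gm <- generate_genome("gm", 50000, 0.5, 30, catalog, seed = 5)
  scm <- fragment_to_scaffolds(gm, min_len = 1000, mean_len = 2000, seed = 6)
  mk <- gm$markers[[1]]
  for (i in seq_len(nrow(mk))) {
    piece <- scm$pieces[scm$pieces$start <= mk$start[i] &
                          scm$pieces$end >= mk$end[i], ]
    expect_equal(nrow(piece), 1)
  }
})

test_that("truth-derived alignments point each mate at the overlapping scaffold", {
  genomes <- low_high_pair()
  rd <- simulate_colony_reads(genomes, even_design(genomes), n_pairs = 400,
                              read_len = 100, insert_mean = 300,
                              insert_sd = 30, error_rate = 0, seed = 13)
  sc <- fragment_to_scaffolds(genomes, min_len = 1000, mean_len = 4000, seed = 14)
  aln <- truth_alignments(rd, sc)
  expect_true(all(aln$aligned_bases >= 30 & aln$aligned_bases <= 100))
  # spot-check: every aligned mate's interval overlaps its scaffold
  pieces <- sc$pieces
  tr <- rd$truth
  for (i in sample(nrow(aln), 50)) {
    row <- aln[i, ]
    t <- tr[tr$read_id == row$read_id, ]
    p <- pieces[pieces$scaffold_id == row$scaffold_id, ]
    iv <- if (row$mate == 1) c(t$start, t$start + 100) else c(t$end - 100, t$end)
    expect_gte(min(iv[2], p$end) - max(iv[1], p$start), row$aligned_bases)
  }
})
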