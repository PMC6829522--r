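# Small reusable fixtures, built in code at test time.

tiny_catalog <- function(n = 20, seed = 11) marker_catalog(n, 60, seed = seed)

# two 80-kbp genomes at nearly equal GC but distinct composition skew:
# the refinement test bed
high_gc_pair <- function(seed = 1, catalog = tiny_catalog(40)) {
  dplyr::bind_rows(
    generate_genome("hgA", 80000, 0.676, 30, catalog, seed = seed,
                    gc_skew = 0.50, at_skew = 0.60),
    generate_genome("hgB", 80000, 0.685, 30, catalog, seed = seed + 1,
                    gc_skew = 0.65, at_skew = 0.40)
  )
}

# two well-separated genomes for simulation tests
low_high_pair <- function(seed = 1, catalog = tiny_catalog()) {
  dplyr::bind_rows(
    generate_genome("lo", 20000, 0.42, 0, catalog, seed = seed),
    generate_genome("hi", 20000, 0.68, 0, catalog, seed = seed + 1)
  )
}

even_design <- function(genomes, sample_ids = "s1") {
  m <- matrix(1, nrow = nrow(genomes), ncol = length(sample_ids),
              dimnames = list(genomes$genome_id, sample_ids))
  abundance_design(m)
}

# scaled-down study conditions for pipeline-level tests: three genomes,
# strong differential design, a few thousand read pairs
small_community <- function(seed = 1) {
  cm <- default_community(seed)
  cm$genome_spec <- tibble::tibble(
    genome_id = c("gA", "gB", "gC"),
    length = 60000L,
    target_gc = c(0.42, 0.54, 0.68),
    gc_skew = c(0.50, 0.55, 0.45),
    at_skew = c(0.50, 0.45, 0.55),
    n_markers = 40L
  )
  cm$catalog_size <- 45L
  cm$design <- matrix(
    c(0.70, 0.10, 0.15,
      0.10, 0.70, 0.15,
      0.20, 0.20, 0.70),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC"), c("colony1", "colony2", "colony3"))
  )
  cm$bulk_weights <- rowMeans(cm$design)
  cm$n_pairs <- 5000L
  cm$bulk_pairs <- 5000L
  cm$scaffold_mean_len <- 4000L
  cm
}

gc_of_reads <- function(rd) {
  r <- rd$reads[[1]]
  compute_gc(c(r$sequence1, r$sequence2))
}

duplicated_markers_for_test <- function(ids, hits, catalog_size) {
  bin_completeness(hits[hits$scaffold_id %in% ids, ], catalog_size)$duplicated
}

random_seq_seeded <- function(n, seed) {
  set.seed(seed)
  random_seq(n)
}

# marker IDs whose planted interval lies within a retained scaffold piece
markers_on_retained <- function(genomes, scaffold_set) {
  out <- character(0)
  for (i in seq_len(nrow(genomes))) {
    mk <- genomes$markers[[i]]
    if (!nrow(mk)) next
    pc <- scaffold_set$pieces[scaffold_set$pieces$genome_id ==
                                genomes$genome_id[i] & scaffold_set$pieces$retained, ]
    keep <- vapply(seq_len(nrow(mk)), function(j) {
      any(pc$start <= mk$start[j] & pc$end >= mk$end[j])
    }, logical(1))
    out <- c(out, mk$marker_id[keep])
  }
  out
}
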