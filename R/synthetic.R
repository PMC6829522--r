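# Synthetic colony communities with planted ground truth. The simulator
# reproduces the statistical structure the downstream analysis relies on:
# genomes of distinct GC and k-mer composition, colony samples in which
# populations are differentially abundant, an MDA amplification step that
# over-samples low-GC fragments, an unbiased bulk sample, scaffold-like
# fragmentation, and planted single-copy marker tags.

#' Generate a synthetic genome with planted marker tags
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = target_gc`; the split of GC
#' between G and C (`gc_skew`) and of AT between A and T (`at_skew`) is
#' genome-specific, which gives each genome its own tetranucleotide signature
#' even when two genomes share nearly the same GC content. `n_markers`
#' distinct catalog tags are planted at uniformly sampled non-overlapping
#' positions; each tag replaces the background bases it covers, so genome
#' length is exact. Background GC is adjusted for the planted tags so the
#' realized genome GC matches `target_gc`.
#'
#' @param genome_id Label for the genome.
#' @param length Genome length in bases (>= 10 kbp).
#' @param target_gc Target GC fraction in `[0, 1]`.
#' @param n_markers Number of distinct catalog markers to plant.
#' @param catalog A [marker_catalog()] with sequences.
#' @param seed Integer seed; the same call with the same seed reproduces the
#'   identical sequence.
#' @param gc_skew Share of G among G+C (default 0.5).
#' @param at_skew Share of A among A+T (default 0.5).
#' @return A one-row tibble: `genome_id`, `length`, `target_gc`, `gc`
#'   (realized), `sequence`, and a `markers` list-column holding a tibble of
#'   (`marker_id`, `start`, `end`) in 0-based half-open coordinates.
#' @export
generate_genome <- function(genome_id, length, target_gc, n_markers = 0,
                            catalog = NULL, seed = 1,
                            gc_skew = 0.5, at_skew = 0.5) {
  if (length < 10000) abort("genome length must be at least 10 kbp")
  if (target_gc < 0 || target_gc > 1) abort("target_gc must lie in [0, 1]")
  if (n_markers > 0 && (is.null(catalog) || n_markers > nrow(catalog))) {
    abort("n_markers exceeds the marker catalog size")
  }
  withr_seed(seed)

  markers <- tibble(marker_id = character(), start = integer(), end = integer())
  marker_seq <- character(0)
  if (n_markers > 0) {
    chosen <- catalog[sort(sample.int(nrow(catalog), n_markers)), ]
    widths <- nchar(chosen$sequence)
    if (sum(widths) > length) {
      abort(sprintf("marker placement failed for genome '%s': tags do not fit", genome_id))
    }
    # exact uniform non-overlapping placement: sorted uniforms on the
    # width-reduced interval, shifted by the cumulative widths
    slack <- length - sum(widths)
    u <- floor(sort(runif(n_markers, 0, slack + 1)))
    u <- pmin(u, slack)
    starts <- as.integer(u + cumsum(c(0, widths[-n_markers])))
    markers <- tibble(marker_id = chosen$marker_id, start = starts,
                      end = starts + widths)
    marker_seq <- chosen$sequence
  }

  # compensate background GC for the planted tags
  marker_gc <- if (length(marker_seq)) sum(gc_fraction(marker_seq) * nchar(marker_seq)) else 0
  bg_len <- length - sum(nchar(marker_seq))
  gc_bg <- if (bg_len > 0) (target_gc * length - marker_gc) / bg_len else target_gc
  gc_bg <- min(max(gc_bg, 0), 1)
  prob <- c((1 - gc_bg) * at_skew, gc_bg * (1 - gc_skew),
            gc_bg * gc_skew, (1 - gc_bg) * (1 - at_skew))
  seq <- random_bases(length, prob)
  for (i in seq_len(nrow(markers))) {
    substr(seq, markers$start[i] + 1L, markers$end[i]) <- marker_seq[i]
  }

  tibble(
    genome_id = genome_id, length = as.integer(length),
    target_gc = target_gc, gc = gc_fraction(seq),
    gc_skew = gc_skew, at_skew = at_skew,
    sequence = seq, markers = list(markers)
  )
}

#' Abundance design for a set of colony samples
#'
#' Normalizes a genome-by-sample weight matrix so every sample column sums
#' to one. Differential-coverage binning is only identifiable when at least
#' one genome varies strongly across samples; a warning is emitted when no
#' genome reaches a max/min cross-sample ratio of 5.
#'
#' @param weights Non-negative genome-by-sample matrix (or data frame) with
#'   genome IDs as row names and sample IDs as column names.
#' @return An `abundance_design` object (normalized matrix plus labels).
#' @export
abundance_design <- function(weights) {
  m <- as.matrix(weights)
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("sample%d", seq_len(ncol(m)))
  if (any(m < 0)) abort("abundance weights must be non-negative")
  csum <- colSums(m)
  if (any(csum == 0)) abort("abundance design has an all-zero sample column")
  m <- sweep(m, 2, csum, "/")
  ratio <- apply(m, 1, function(r) max(r) / min(r))
  if (ncol(m) >= 2 && !any(ratio >= 5)) {
    warn("no genome has a cross-sample abundance ratio >= 5; differential-coverage binning may be unidentifiable")
  }
  structure(
    list(matrix = m, genome_ids = rownames(m), sample_ids = colnames(m)),
    class = "abundance_design"
  )
}

#' MDA amplification-bias model
#'
#' Multiple displacement amplification preferentially amplifies low-GC
#' fragments. The simulator models this at fragment acceptance: a proposed
#' fragment of GC fraction `g` is accepted with probability proportional to
#' `exp(-beta * (g - reference_gc))`, a single-parameter, strictly
#' GC-decreasing weight. `beta = 0` gives uniform (unbiased) sampling.
#'
#' @param beta Non-negative bias strength.
#' @param reference_gc GC fraction at which the weight equals 1 (default 0.5).
#' @return An `mda_bias_model` object.
#' @export
mda_bias_model <- function(beta = 0, reference_gc = 0.5) {
  if (beta < 0) abort("bias strength beta must be non-negative")
  structure(list(beta = beta, reference_gc = reference_gc), class = "mda_bias_model")
}

#' Fragment acceptance weights under an MDA bias model
#'
#' @param model An [mda_bias_model()].
#' @param gc Numeric vector of fragment GC fractions.
#' @return Positive weights, strictly decreasing in `gc` when `beta > 0`.
#' @export
bias_weight <- function(model, gc) {
  exp(-model$beta * (gc - model$reference_gc))
}

default_quality_means <- function(read_len) {
  # Illumina-like profile: high early-cycle quality decaying towards the tail
  seq(37, 31, length.out = read_len)
}

make_qualities <- function(n, read_len, means, sd = 2) {
  q <- round(rnorm(n * read_len, mean = rep(means, times = n), sd = sd))
  q <- pmin(pmax(q, 2L), 40L)
  phred_encode(q, rep(read_len, n))
}

inject_errors <- function(seqs, rate) {
  if (rate == 0 || length(seqs) == 0) return(seqs)
  read_len <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  mask <- runif(length(m)) < rate
  if (any(mask)) {
    idx <- match(m[mask], DNA_BASES)
    shift <- sample.int(3, sum(mask), replace = TRUE)
    m[mask] <- DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

simulate_sample_pairs <- function(genomes, weights, n_pairs, read_len,
                                  insert_mean, insert_sd, bias) {
  glen <- genomes$length
  acc_est <- 0.5
  gis <- sts <- ens <- integer(0)
  while (length(gis) < n_pairs) {
    need <- n_pairs - length(gis)
    m <- max(2000L, ceiling(need / acc_est * 1.3))
    gi <- sample.int(nrow(genomes), m, replace = TRUE, prob = weights)
    len <- pmax(read_len, pmin(as.integer(round(rnorm(m, insert_mean, insert_sd))), glen[gi]))
    st <- as.integer(floor(runif(m) * (glen[gi] - len + 1)))
    en <- st + len
    if (bias$beta > 0) {
      gc <- gc_fraction(substr0(genomes$sequence[gi], st, en))
      w <- bias_weight(bias, gc)
      keep <- runif(m) < w / max(w)
      acc_est <- max(mean(keep), 0.05)
    } else {
      keep <- rep(TRUE, m)
    }
    gis <- c(gis, gi[keep]); sts <- c(sts, st[keep]); ens <- c(ens, en[keep])
  }
  idx <- seq_len(n_pairs)
  list(gi = gis[idx], start = sts[idx], end = ens[idx])
}

#' Simulate paired-end colony reads under differential abundance and MDA bias
#'
#' For every sample in the design, fragments are drawn genome-proportionally
#' to the design weights and accepted with probability proportional to
#' `exp(-beta * (fragment_gc - reference_gc))` (the MDA bias model); the two
#' fragment ends become the read pair (mate 2 reverse-complemented), with
#' i.i.d. per-base substitution errors at `error_rate` and Phred+33 quality
#' strings drawn around a per-position profile. Every pair is recorded in a
#' truth table with its source genome and fragment coordinates.
#'
#' @param genomes Genome tibble from [generate_genome()] rows.
#' @param design An [abundance_design()] whose genome IDs match `genomes`.
#' @param n_pairs Read pairs per sample (>= 1).
#' @param read_len Read length in bases (must be below `insert_mean`).
#' @param insert_mean,insert_sd Fragment (insert) length distribution.
#' @param error_rate Per-base substitution error rate.
#' @param bias An [mda_bias_model()].
#' @param seed Integer seed.
#' @param quality_means Optional numeric vector (length `read_len`) of mean
#'   Phred scores per position.
#' @return A `colony_reads` object: `reads` (a named list of per-sample
#'   tibbles with `read_id`, `sequence1`, `quality1`, `sequence2`,
#'   `quality2`) and `truth` (tibble `sample_id`, `read_id`, `genome_id`,
#'   `start`, `end`, 0-based half-open fragment coordinates).
#' @export
simulate_colony_reads <- function(genomes, design, n_pairs = 50000,
                                  read_len = 150, insert_mean = 600,
                                  insert_sd = 60, error_rate = 0.005,
                                  bias = mda_bias_model(0), seed = 1,
                                  quality_means = NULL) {
  stopifnot(inherits(design, "abundance_design"))
  if (n_pairs < 1) abort("n_pairs must be at least 1")
  if (read_len >= insert_mean) abort("read_len must be smaller than insert_mean")
  if (!setequal(design$genome_ids, genomes$genome_id)) {
    abort("design genome IDs do not match the genome set")
  }
  genomes <- genomes[match(design$genome_ids, genomes$genome_id), ]
  if (is.null(quality_means)) quality_means <- default_quality_means(read_len)
  withr_seed(seed)

  reads <- list()
  truth <- list()
  for (s in design$sample_ids) {
    w <- design$matrix[, s]
    if (sum(w) == 0) abort(sprintf("sample '%s' has an all-zero abundance column", s))
    frag <- simulate_sample_pairs(genomes, w, n_pairs, read_len,
                                  insert_mean, insert_sd, bias)
    m1 <- substr0(genomes$sequence[frag$gi], frag$start, frag$start + read_len)
    m2 <- revcomp(substr0(genomes$sequence[frag$gi], frag$end - read_len, frag$end))
    m1 <- inject_errors(m1, error_rate)
    m2 <- inject_errors(m2, error_rate)
    ids <- sprintf("%s_%06d", s, seq_len(n_pairs))
    reads[[s]] <- tibble(
      read_id = ids,
      sequence1 = m1, quality1 = make_qualities(n_pairs, read_len, quality_means),
      sequence2 = m2, quality2 = make_qualities(n_pairs, read_len, quality_means)
    )
    truth[[s]] <- tibble(
      sample_id = s, read_id = ids,
      genome_id = genomes$genome_id[frag$gi],
      start = frag$start, end = frag$end
    )
  }
  structure(
    list(reads = reads, truth = bind_rows(truth),
         read_len = read_len, bias = bias),
    class = "colony_reads"
  )
}

#' Simulate an unamplified bulk sample
#'
#' Identical to [simulate_colony_reads()] with the MDA bias forced to zero:
#' the bulk sample is the unbiased reference against which amplification
#' bias is estimated.
#'
#' @param genomes Genome tibble.
#' @param weights Named per-genome weight vector (or unnamed, in genome
#'   order) giving the bulk community composition.
#' @param n_pairs Read pairs.
#' @param sample_id Sample label (default "bulk").
#' @param ... Passed to [simulate_colony_reads()] (`read_len`, `error_rate`,
#'   `seed`, ...). Any `bias` argument is overridden with `beta = 0`.
#' @return A `colony_reads` object with one sample.
#' @export
simulate_bulk_reads <- function(genomes, weights, n_pairs = 50000,
                                sample_id = "bulk", ...) {
  if (is.null(names(weights))) names(weights) <- genomes$genome_id
  m <- matrix(weights[genomes$genome_id], ncol = 1,
              dimnames = list(genomes$genome_id, sample_id))
  args <- list(...)
  args$bias <- mda_bias_model(0)
  do.call(simulate_colony_reads,
          c(list(genomes = genomes, design = abundance_design(m),
                 n_pairs = n_pairs), args))
}

#' Write simulated reads to paired FASTQ files
#'
#' One `<prefix><sample>_R1.fastq` / `_R2.fastq` pair per sample, Phred+33.
#'
#' @param x A `colony_reads` object.
#' @param outdir Output directory (created if missing).
#' @param prefix Filename prefix (default "").
#' @return Tibble of written paths, invisibly.
#' @export
write_reads <- function(x, outdir, prefix = "") {
  stopifnot(inherits(x, "colony_reads"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map(names(x$reads), function(s) {
    r <- x$reads[[s]]
    p1 <- file.path(outdir, sprintf("%s%s_R1.fastq", prefix, s))
    p2 <- file.path(outdir, sprintf("%s%s_R2.fastq", prefix, s))
    write_fastq_tbl(tibble(read_id = r$read_id, sequence = r$sequence1,
                           quality = r$quality1), p1)
    write_fastq_tbl(tibble(read_id = r$read_id, sequence = r$sequence2,
                           quality = r$quality2), p2)
    tibble(sample_id = s, r1 = p1, r2 = p2)
  })
  invisible(bind_rows(paths))
}

#' Fragment genomes into scaffold-like pieces
#'
#' Cuts each genome at geometrically spaced breakpoints (mean spacing
#' `mean_len`), discards pieces shorter than `min_len` (they never enter a
#' real assembly), and records every piece's genome of origin and
#' coordinates. Geometric spacing produces the wide scaffold-length
#' distribution of real metagenome assemblies. By default breakpoints that
#' would fall inside a planted marker interval are moved past the marker, so
#' marker-based completeness truth stays exact; `avoid_marker_split = FALSE`
#' allows splitting for sensitivity tests.
#'
#' @param genomes Genome tibble from [generate_genome()] rows.
#' @param min_len Minimum retained scaffold length (>= 1000).
#' @param mean_len Mean piece length (must be >= `min_len`).
#' @param seed Integer seed.
#' @param avoid_marker_split Keep breakpoints out of marker intervals.
#' @return A `scaffold_set`: `scaffolds` (retained pieces with sequence;
#'   columns `scaffold_id`, `genome_id`, `start`, `end`, `length`,
#'   `sequence`), `pieces` (all pieces, retained flag, no sequence), `truth`
#'   (`scaffold_id` to `genome_id`), and `discarded_fraction`
#'   (length-weighted share of genome sequence discarded).
#' @export
fragment_to_scaffolds <- function(genomes, min_len = 1000, mean_len = 5000,
                                  seed = 1, avoid_marker_split = TRUE) {
  if (min_len < 1000) abort("min_len must be at least 1 kbp")
  if (mean_len < min_len) abort("mean_len must be >= min_len")
  withr_seed(seed)

  pieces <- purrr::map(seq_len(nrow(genomes)), function(i) {
    L <- genomes$length[i]
    lens <- 1L + stats::rgeom(ceiling(L / mean_len * 3) + 10, prob = 1 / mean_len)
    bp <- cumsum(lens)
    bp <- bp[bp < L]
    if (avoid_marker_split) {
      mk <- genomes$markers[[i]]
      if (nrow(mk)) {
        for (j in seq_along(bp)) {
          inside <- mk$start < bp[j] & bp[j] < mk$end
          if (any(inside)) bp[j] <- mk$end[which(inside)[1]]
        }
        bp <- sort(unique(bp[bp < L]))
      }
    }
    start <- c(0L, as.integer(bp))
    end <- c(as.integer(bp), L)
    tibble(
      genome_id = genomes$genome_id[i],
      scaffold_id = sprintf("%s_s%04d", genomes$genome_id[i], seq_along(start)),
      start = start, end = end, length = end - start,
      retained = (end - start) >= min_len
    )
  }) |> bind_rows()

  retained <- pieces |> filter(.data$retained)
  gseq <- setNames(genomes$sequence, genomes$genome_id)
  scaffolds <- retained |>
    mutate(sequence = substr0(gseq[.data$genome_id], .data$start, .data$end)) |>
    select("scaffold_id", "genome_id", "start", "end", "length", "sequence")

  structure(
    list(
      scaffolds = scaffolds,
      pieces = pieces,
      truth = scaffolds |> select("scaffold_id", "genome_id"),
      discarded_fraction = 1 - sum(retained$length) / sum(pieces$length)
    ),
    class = "scaffold_set"
  )
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf(
    "<scaffold_set> %d scaffolds from %d genomes (%.1f%% of genome length discarded as < min_len)\n",
    nrow(x$scaffolds), dplyr::n_distinct(x$scaffolds$genome_id),
    100 * x$discarded_fraction
  ))
  invisible(x)
}

#' Derive read-to-scaffold alignments from simulation truth
#'
#' In synthetic mode the aligner is bypassed: each mate's genomic interval is
#' known from the truth table, so it is assigned to the retained scaffold
#' piece with the largest overlap (the alignment a mapper would report),
#' provided the overlap reaches `min_aligned` bases. Mates falling entirely
#' in discarded (sub-minimum-length) pieces go unmapped, as they would
#' against a real assembly.
#'
#' @param reads A `colony_reads` object (or its `truth` tibble).
#' @param scaffold_set A `scaffold_set` from [fragment_to_scaffolds()].
#' @param read_len Read length; taken from `reads` when it is a
#'   `colony_reads` object.
#' @param min_aligned Minimum overlap to count as mapped (default 30).
#' @return Alignment tibble: `sample_id`, `read_id`, `scaffold_id`,
#'   `aligned_bases`, `mate` (1 or 2).
#' @export
truth_alignments <- function(reads, scaffold_set, read_len = NULL,
                             min_aligned = 30) {
  truth <- if (inherits(reads, "colony_reads")) reads$truth else reads
  if (is.null(read_len)) {
    if (!inherits(reads, "colony_reads")) abort("read_len is required with a bare truth table")
    read_len <- reads$read_len
  }
  pieces <- scaffold_set$pieces

  one_genome <- function(tr, pc) {
    ps <- pc$start; pe <- pc$end; pr <- pc$retained; pid <- pc$scaffold_id
    assign_mate <- function(s, e, mate) {
      j <- findInterval(s, ps)
      j <- pmax(j, 1L)
      best_ov <- rep(-1L, length(s)); best_k <- j
      for (d in 0:2) {
        k <- pmin(j + d, length(ps))
        ov <- pmin(e, pe[k]) - pmax(s, ps[k])
        ov[!pr[k]] <- -1L
        upd <- ov > best_ov
        best_ov[upd] <- ov[upd]; best_k[upd] <- k[upd]
      }
      keep <- best_ov >= min_aligned
      tibble(
        sample_id = tr$sample_id[keep], read_id = tr$read_id[keep],
        scaffold_id = pid[best_k[keep]],
        aligned_bases = pmin(best_ov[keep], read_len), mate = mate
      )
    }
    bind_rows(
      assign_mate(tr$start, tr$start + read_len, 1L),
      assign_mate(tr$end - read_len, tr$end, 2L)
    )
  }

  split(truth, truth$genome_id) |>
    purrr::imap(function(tr, g) one_genome(tr, pieces[pieces$genome_id == g, ])) |>
    bind_rows() |>
    arrange(.data$sample_id, .data$read_id, .data$mate)
}

#' Simulate replicate genus-abundance profiles
#'
#' Emulates the replicate-similarity design: `n_species` colony species,
#' each with `n_replicates` sampled colonies. Species base profiles are
#' drawn from a flat Dirichlet over `n_genera` genera; replicates multiply
#' the base profile by i.i.d. log-normal noise (`noise_sd` on the log scale)
#' and renormalize, so within-species distances stay well below
#' between-species distances.
#'
#' @param n_species,n_replicates,n_genera Design dimensions.
#' @param noise_sd Log-scale replicate noise (default 0.3).
#' @param seed Integer seed.
#' @return Tibble with `sample_id` plus one relative-abundance column per
#'   genus; rows sum to 1.
#' @export
simulate_replicate_profiles <- function(n_species = 3, n_replicates = 2,
                                        n_genera = 30, noise_sd = 0.3,
                                        seed = 1) {
  withr_seed(seed)
  genera <- sprintf("genus%02d", seq_len(n_genera))
  rows <- list()
  for (i in seq_len(n_species)) {
    base <- stats::rexp(n_genera)
    base <- base / sum(base)
    for (r in seq_len(n_replicates)) {
      p <- base * exp(rnorm(n_genera, 0, noise_sd))
      p <- p / sum(p)
      rows[[sprintf("species%d_rep%d", i, r)]] <- p
    }
  }
  out <- as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(out) <- genera
  dplyr::bind_cols(tibble(sample_id = names(rows)), out)
}

#' Default synthetic colony community (the package's study conditions)
#'
#' Five 200-kbp genomes spanning GC 0.42-0.685 (the range seen across
#' single-colony population bins), three colony samples with strongly
#' differential abundance vectors, two of the genomes (GC 0.676 / 0.685)
#' sharing an identical abundance vector so that only composition-based
#' refinement can separate them, MDA bias `beta = 2`, 50 000 read pairs per
#' colony sample plus an unbiased bulk sample at the pooled composition,
#' and 105 of 107 catalog markers planted per genome.
#'
#' @param seed Integer seed controlling every stage.
#' @return A named list of simulation parameters consumed by
#'   [run_pipeline()] and the simulation stages.
#' @export
default_community <- function(seed = 1) {
  design <- matrix(
    c(0.45, 0.05, 0.10,
      0.05, 0.45, 0.10,
      0.05, 0.05, 0.50,
      0.225, 0.225, 0.15,
      0.225, 0.225, 0.15),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("g", 1:5),
                    c("aeruginosa", "wesenbergii", "panniformis"))
  )
  list(
    genome_spec = tibble(
      genome_id = paste0("g", 1:5),
      length = 200000L,
      target_gc = c(0.42, 0.50, 0.54, 0.676, 0.685),
      gc_skew = c(0.50, 0.45, 0.55, 0.50, 0.65),
      at_skew = c(0.50, 0.55, 0.45, 0.60, 0.40),
      n_markers = 105L
    ),
    catalog_size = 107L,
    marker_tag_length = 60L,
    design = design,
    bulk_weights = rowMeans(design),
    beta = 2,
    n_pairs = 50000L,
    bulk_pairs = 50000L,
    read_len = 150L,
    insert_mean = 600,
    insert_sd = 60,
    error_rate = 0.005,
    scaffold_min_len = 1000L,
    scaffold_mean_len = 5000L,
    seed = seed
  )
}
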