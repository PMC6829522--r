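# End-to-end orchestration: simulate -> trim -> profile -> factors -> bin ->
# refine -> assess -> report, with seeds and parameters recorded in a
# manifest so a rerun with the same config reproduces every table.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. In synthetic mode the
#' community definition (see [default_community()]) drives simulation; in
#' real-data mode `scaffolds_path` (FASTA), `coverage_path` (TSV:
#' `scaffold_id` + one depth column per sample) and optionally
#' `marker_hits_path` are read instead, and the simulation stages are
#' skipped.
#'
#' @param outdir Output directory.
#' @param seed Master seed; all stage seeds derive from it.
#' @param community Synthetic community definition (default
#'   [default_community()] at `seed`).
#' @param mode "synthetic" or "real".
#' @param scaffolds_path,coverage_path,marker_hits_path Real-data inputs.
#' @param trim A [trim_policy()].
#' @param pseudocount,neighborhood_radius,min_cluster_size,max_duplicated
#'   Binning-stage parameters.
#' @param min_aligned Minimum overlap for a truth-derived alignment.
#' @param write_fastq Write simulated reads as FASTQ (can be disabled to
#'   save time and disk when only tables are needed).
#' @return A `colonybin_config` list.
#' @export
colonybin_config <- function(outdir = tempfile("colonybin_"), seed = 1,
                             community = default_community(seed),
                             mode = c("synthetic", "real"),
                             scaffolds_path = NULL, coverage_path = NULL,
                             marker_hits_path = NULL,
                             trim = trim_policy(),
                             pseudocount = 0.01,
                             neighborhood_radius = 0.3,
                             min_cluster_size = 10,
                             max_duplicated = 5,
                             min_aligned = 30,
                             write_fastq = TRUE) {
  structure(
    list(outdir = outdir, seed = seed, community = community,
         mode = match.arg(mode),
         scaffolds_path = scaffolds_path, coverage_path = coverage_path,
         marker_hits_path = marker_hits_path,
         trim = trim, pseudocount = pseudocount,
         neighborhood_radius = neighborhood_radius,
         min_cluster_size = min_cluster_size,
         max_duplicated = max_duplicated, min_aligned = min_aligned,
         write_fastq = write_fastq),
    class = "colonybin_config"
  )
}

#' Run the single-colony binning pipeline
#'
#' Executes the stages in order, logging each stage's parameters and
#' timing; a rerun with the same config reproduces byte-identical tables.
#' A stage failure aborts with the failing stage named.
#'
#' @param config A [colonybin_config()].
#' @return A `colonybin_run`: the bin set, per-scaffold profiles, coverage
#'   matrix, standardization factors, evaluation against planted truth
#'   (synthetic mode), assembly stats, and the manifest.
#' @export
run_pipeline <- function(config = colonybin_config()) {
  stopifnot(inherits(config, "colonybin_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "pipeline.log")
  manifest <- list(seed = config$seed, mode = config$mode, stages = list())
  state <- new.env(parent = emptyenv())

  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(name = name, seconds = round(dt, 2))
    cat(sprintf("[%s] stage %-10s %.1fs\n", format(Sys.time(), "%H:%M:%S"),
                name, dt), file = log_path, append = TRUE)
    res
  }

  if (config$mode == "synthetic") {
    run_synthetic_stages(config, state, stage)
  } else {
    run_real_input_stages(config, state, stage)
  }

  # profile: per-scaffold features and assembly stats
  stage("profile", function() {
    state$profiles <- scaffold_profiles(state$scaffolds)
    state$n50 <- compute_n50(state$profiles$length)
    if (!is.null(state$alignments)) {
      state$coverage <- coverage_matrix(
        state$alignments, state$profiles[, c("scaffold_id", "length")],
        sample_ids = state$binning_samples
      )
    }
    write_tsv_table(left_join(state$profiles, state$coverage, by = "scaffold_id"),
                    file.path(config$outdir, "scaffold_profiles.tsv"))
  })

  # factors: GC standardization from amplified vs bulk mapped reads
  stage("factors", function() {
    state$factors <- if (!is.null(state$bulk_reads_per_scaffold)) {
      amp <- state$reads_per_scaffold |>
        group_by(.data$scaffold_id) |>
        summarise(mapped_reads = sum(.data$mapped_reads), .groups = "drop") |>
        left_join(state$profiles, by = "scaffold_id")
      blk <- state$bulk_reads_per_scaffold |>
        left_join(state$profiles, by = "scaffold_id")
      standardization_factors(
        gc_histogram(amp$gc, amp$mapped_reads),
        gc_histogram(blk$gc, blk$mapped_reads)
      )
    } else {
      NULL
    }
    if (!is.null(state$factors)) {
      write_tsv_table(as_tibble(state$factors),
                      file.path(config$outdir, "standardization_factors.tsv"))
    }
  })

  # bin: density clustering in log-coverage space plus composition refinement
  stage("bin", function() {
    space <- coverage_space(state$coverage, config$pseudocount,
                            allow_n = length(state$binning_samples) != 3)
    labels <- cluster_scaffolds(space, config$min_cluster_size,
                                config$neighborhood_radius)
    tnf <- compute_tnf(setNames(state$scaffolds$sequence,
                                state$scaffolds$scaffold_id))
    gc <- setNames(state$profiles$gc, state$profiles$scaffold_id)
    state$membership <- refine_bins(
      labels, gc, tnf, state$marker_hits,
      lengths = setNames(state$profiles$length, state$profiles$scaffold_id),
      max_duplicated = config$max_duplicated,
      catalog_size = state$catalog_size
    )
  })

  # assess: per-bin statistics and quality flags
  bin_set <- stage("assess", function() {
    bs <- assemble_bins(state$membership, state$profiles, state$marker_hits,
                        state$catalog_size,
                        mapped_reads = state$reads_per_scaffold,
                        factors = state$factors)
    write_tsv_table(bs$bins, file.path(config$outdir, "bin_summary.tsv"))
    for (b in bs$bins$bin_id) {
      ids <- bs$members$scaffold_id[bs$members$bin_id == b]
      write_fasta_tbl(state$scaffolds[state$scaffolds$scaffold_id %in% ids, ],
                      file.path(config$outdir, paste0(b, ".fasta")),
                      id_col = "scaffold_id")
    }
    bs
  })

  # report: evaluation against planted truth and bin read-pair extraction
  result <- stage("report", function() {
    evaluation <- NULL
    if (!is.null(state$truth)) {
      evaluation <- evaluate_bins(bin_set, state$truth,
                                  state$profiles[, c("scaffold_id", "length")])
      write_tsv_table(evaluation, file.path(config$outdir, "evaluation.tsv"))
    }
    bin_pairs <- NULL
    if (!is.null(state$alignments)) {
      bin_pairs <- purrr::map(
        setNames(bin_set$bins$bin_id, bin_set$bins$bin_id),
        function(b) extract_bin_reads(
          state$alignments,
          bin_set$members$scaffold_id[bin_set$members$bin_id == b]
        )
      )
      for (b in names(bin_pairs)) {
        write_tsv_table(bin_pairs[[b]],
                        file.path(config$outdir, paste0(b, "_read_pairs.tsv")))
      }
    }
    list(evaluation = evaluation, bin_pairs = bin_pairs)
  })

  manifest$parameters <- config[setdiff(names(config), c("community", "trim"))]
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(
    list(
      bin_set = bin_set, profiles = state$profiles, coverage = state$coverage,
      factors = state$factors, evaluation = result$evaluation,
      bin_pairs = result$bin_pairs, n50 = state$n50,
      trim_counts = state$trim_counts, truth = state$truth,
      genomes = state$genomes, scaffold_set = state$scaffold_set,
      manifest = manifest, outdir = config$outdir, config = config
    ),
    class = "colonybin_run"
  )
}

# synthetic-mode front half: simulate genomes/reads, trim, fragment,
# derive truth alignments
run_synthetic_stages <- function(config, state, stage) {
  cm <- config$community

  stage("simulate", function() {
    state$catalog <- marker_catalog(cm$catalog_size, cm$marker_tag_length,
                                    seed = cm$seed)
    state$catalog_size <- cm$catalog_size
    state$genomes <- purrr::pmap(
      cm$genome_spec,
      function(genome_id, length, target_gc, gc_skew, at_skew, n_markers) {
        generate_genome(genome_id, length, target_gc, n_markers,
                        state$catalog, seed = cm$seed + match(genome_id, cm$genome_spec$genome_id),
                        gc_skew = gc_skew, at_skew = at_skew)
      }
    ) |> bind_rows()
    design <- abundance_design(cm$design)
    state$binning_samples <- design$sample_ids
    state$colony <- simulate_colony_reads(
      state$genomes, design, cm$n_pairs, cm$read_len, cm$insert_mean,
      cm$insert_sd, cm$error_rate, mda_bias_model(cm$beta),
      seed = cm$seed + 100
    )
    state$bulk <- simulate_bulk_reads(
      state$genomes, cm$bulk_weights, cm$bulk_pairs,
      read_len = cm$read_len, insert_mean = cm$insert_mean,
      insert_sd = cm$insert_sd, error_rate = cm$error_rate,
      seed = cm$seed + 200
    )
    if (config$write_fastq) {
      write_reads(state$colony, file.path(config$outdir, "reads"))
      write_reads(state$bulk, file.path(config$outdir, "reads"))
    }
  })

  stage("trim", function() {
    keep_pairs <- function(reads_obj) {
      purrr::imap(reads_obj$reads, function(r, s) {
        tr <- trim_pairs(
          tibble(read_id = r$read_id, sequence = r$sequence1, quality = r$quality1),
          tibble(read_id = r$read_id, sequence = r$sequence2, quality = r$quality2),
          config$trim
        )
        list(surviving = tr$pairs$read_id, counts = mutate(tr$counts, sample_id = s))
      })
    }
    colony_trim <- keep_pairs(state$colony)
    bulk_trim <- keep_pairs(state$bulk)
    state$trim_counts <- bind_rows(
      c(purrr::map(unname(colony_trim), "counts"),
        purrr::map(unname(bulk_trim), "counts"))
    )
    state$surviving <- c(purrr::map(colony_trim, "surviving"),
                         purrr::map(bulk_trim, "surviving"))
    write_tsv_table(state$trim_counts, file.path(config$outdir, "trim_counts.tsv"))
  })

  stage("scaffolds", function() {
    state$scaffold_set <- fragment_to_scaffolds(
      state$genomes, cm$scaffold_min_len, cm$scaffold_mean_len,
      seed = cm$seed + 300
    )
    state$scaffolds <- state$scaffold_set$scaffolds
    state$truth <- state$scaffold_set$truth
    write_fasta_tbl(state$scaffolds, file.path(config$outdir, "scaffolds.fasta"),
                    id_col = "scaffold_id")
    write_tsv_table(state$truth, file.path(config$outdir, "scaffold_truth.tsv"))

    # truth-derived alignments, restricted to pairs surviving trimming
    # (orphan survivors are excluded from binning coverage)
    survived <- function(tr) {
      tr[tr$read_id %in% state$surviving[[tr$sample_id[1]]], ]
    }
    colony_truth <- split(state$colony$truth, state$colony$truth$sample_id) |>
      purrr::map(survived) |> bind_rows()
    state$alignments <- truth_alignments(colony_truth, state$scaffold_set,
                                         read_len = cm$read_len,
                                         min_aligned = config$min_aligned)
    bulk_truth <- split(state$bulk$truth, state$bulk$truth$sample_id) |>
      purrr::map(survived) |> bind_rows()
    bulk_aln <- truth_alignments(bulk_truth, state$scaffold_set,
                                 read_len = cm$read_len,
                                 min_aligned = config$min_aligned)
    state$reads_per_scaffold <- state$alignments |>
      count(.data$scaffold_id, .data$sample_id, name = "mapped_reads")
    state$bulk_reads_per_scaffold <- bulk_aln |>
      count(.data$scaffold_id, name = "mapped_reads")
    state$marker_hits <- detect_markers(state$scaffolds, state$catalog)
  })

  invisible(NULL)
}

# real-data-mode front half: read scaffolds, coverage and marker hits
run_real_input_stages <- function(config, state, stage) {
  stage("inputs", function() {
    for (p in c(scaffolds = config$scaffolds_path, coverage = config$coverage_path)) {
      if (is.null(p) || !file.exists(p)) {
        abort(sprintf("required input missing: %s", p %||% "(path not set)"))
      }
    }
    fa <- read_fasta_tbl(config$scaffolds_path)
    state$scaffolds <- tibble(scaffold_id = fa$id, sequence = fa$sequence)
    cov <- read_tsv_table(config$coverage_path)
    state$coverage_table <- cov
    state$binning_samples <- setdiff(names(cov), "scaffold_id")
    state$marker_hits <- if (!is.null(config$marker_hits_path)) {
      import_marker_hits(config$marker_hits_path)
    } else {
      tibble(scaffold_id = character(), marker_id = character(), count = integer())
    }
    state$catalog_size <- 107L
    state$truth <- NULL
    state$alignments <- NULL
    state$reads_per_scaffold <- NULL
    state$bulk_reads_per_scaffold <- NULL
  })

  stage("coverage", function() {
    # real mode takes mean depths as given
    state$coverage <- state$coverage_table
  })
  invisible(NULL)
}

#' @export
print.colonybin_run <- function(x, ...) {
  cat(sprintf("<colonybin_run> %d bins, N50 %d bp, outputs in %s\n",
              nrow(x$bin_set$bins), x$n50, x$outdir))
  print(x$bin_set$bins)
  invisible(x)
}

#' Bin report with optional truth evaluation
#'
#' One row per bin with the draft-genome accounting columns; when planted
#' truth is supplied, length-weighted per-genome precision and recall are
#' attached to each genome's majority bin.
#'
#' @param bin_set A `bin_set` (or `colonybin_run`).
#' @param truth Optional truth tibble (`scaffold_id`, `genome_id`).
#' @param lengths Tibble (`scaffold_id`, `length`); required with `truth`.
#' @return Tibble of bins (+ `genome_id`, `recall`, `precision` with truth).
#' @export
bin_report <- function(bin_set, truth = NULL, lengths = NULL) {
  if (inherits(bin_set, "colonybin_run")) {
    if (is.null(truth)) truth <- bin_set$truth
    if (is.null(lengths)) lengths <- bin_set$profiles[, c("scaffold_id", "length")]
    bin_set <- bin_set$bin_set
  }
  if (nrow(bin_set$bins) == 0) abort("bin set is empty")
  out <- bin_set$bins
  if (!is.null(truth)) {
    if (is.null(lengths)) abort("lengths are required to evaluate against truth")
    ev <- evaluate_bins(bin_set, truth, lengths)
    out <- left_join(out, ev, by = "bin_id")
  }
  out
}

#' Problem-specific coverage profile for the profile stage of real data
#'
#' Convenience wrapper: compute per-sample mean depths from an alignment
#' table read from disk (TSV with `read_id`, `scaffold_id`,
#' `aligned_bases`, `mate`, `sample_id`).
#'
#' @param alignment_path Path to the alignment TSV.
#' @param scaffolds Tibble with `scaffold_id` and `sequence` (or `length`).
#' @return Coverage tibble (`scaffold_id` + one column per sample).
#' @export
coverage_from_table <- function(alignment_path, scaffolds) {
  aln <- read_tsv_table(alignment_path)
  len <- if ("length" %in% names(scaffolds)) {
    scaffolds[, c("scaffold_id", "length")]
  } else {
    tibble(scaffold_id = scaffolds$scaffold_id, length = nchar(scaffolds$sequence))
  }
  coverage_matrix(aln, len)
}
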