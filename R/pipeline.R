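# ---- pipeline stages -------------------------------------------------------

log_row <- function(stage, detail, n_in, n_kept, seed = NA_integer_) {
  tibble::tibble(stage = stage, detail = detail,
                 records_in = as.integer(n_in),
                 records_kept = as.integer(n_kept),
                 records_excluded = as.integer(n_in - n_kept),
                 seed = as.integer(seed))
}

#' Generate a full synthetic study into a directory
#'
#' Writes a photometry stream, a region ontology + count table, and a
#' per-cell intensity table, each with its ground-truth file, as
#' delimited/structured text. The `"null"` preset uses a global-null
#' region design (no effect regions); the `"effect"` preset plants a
#' 3-fold recall-group effect in 10 of 100 regions.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed; sub-generators use fixed offsets.
#' @param preset `"null"` or `"effect"`.
#' @return Invisibly, the run-log tibble.
#' @export
run_simulate <- function(out_dir, seed = 0, preset = c("null", "effect")) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)

  pconf <- photometry_config(
    duration_s = 300,
    transients = list(`465` = transient_preset("FR", onset_s = 90)),
    event_channel = "560", event_rate_hz = 2 / 60,
    event_amplitude = 0.3, event_tau_s = 3,
    bleach_slope_per_s = -2e-4, motion_artifact_sd = 0.05,
    noise_sd = 0.005, seed = seed
  )
  psim <- simulate_photometry(pconf)

  rconf <- region_sim_config(
    n_regions = 100,
    effect_regions = if (preset == "effect") 1:10 else integer(),
    effect_multiplier = if (preset == "effect") 3 else 1,
    n_ventricular = 10, n_aggregate = 5,
    seed = seed + 1L
  )
  rsim <- simulate_region_counts(rconf)

  csim <- simulate_cell_table(cell_sim_config(seed = seed + 2L))

  write_table(psim$stream, file.path(out_dir, "stream.csv"))
  write_truth(list(transients = lapply(psim$truth$transients, as.data.frame),
                   event_channel = psim$truth$event_channel,
                   event_times = psim$truth$event_times,
                   seed = seed),
              file.path(out_dir, "truth_photometry.json"))
  write_table(rsim$counts, file.path(out_dir, "region_counts.csv"))
  write_table(rsim$subjects, file.path(out_dir, "subjects.csv"))
  write_ontology(rsim$ontology, file.path(out_dir, "ontology.json"))
  write_truth(rsim$truth, file.path(out_dir, "truth_regions.json"))
  write_table(csim$cells, file.path(out_dir, "cell_table.csv"))
  write_truth(csim$truth, file.path(out_dir, "truth_cells.json"))

  log <- dplyr::bind_rows(
    log_row("simulate", "photometry_stream", nrow(psim$stream),
            nrow(psim$stream), seed),
    log_row("simulate", paste0("region_counts_", preset), nrow(rsim$counts),
            nrow(rsim$counts), seed + 1L),
    log_row("simulate", "cell_table", nrow(csim$cells), nrow(csim$cells),
            seed + 2L)
  )
  write_table(log, file.path(out_dir, "run_log.csv"))
  invisible(log)
}

#' Run the photometry chain on a raw stream file
#'
#' Demultiplexes the stream, then for each signal channel: moving-average
#' smoothing, linear bleach correction, isosbestic-referenced dF/F
#' against the reference channel, and transient metrics. The calcium
#' channel (if present) is additionally band-pass filtered and run
#' through threshold event detection, with the baseline window doubling
#' as the quiescent noise window.
#'
#' @param in_path Stream CSV (`time_s`, `value`).
#' @param out_dir Output directory.
#' @param schedule A [pulse_schedule()].
#' @param baseline_window_s `(start, end)` of the quiet pre-context
#'   baseline, seconds.
#' @param reference_channel Isosbestic channel id.
#' @param ca_channel Calcium channel id (`NULL` to skip event detection).
#' @param smooth_window Moving-average width, samples (odd).
#' @return Invisibly, the run-log tibble.
#' @export
run_photometry <- function(in_path, out_dir, schedule = pulse_schedule(),
                           baseline_window_s = c(0, 60),
                           reference_channel = "405", ca_channel = "560",
                           smooth_window = 5) {
  stream <- load_table(in_path, "stream")
  traces <- demultiplex(stream, schedule)
  if (!reference_channel %in% names(traces)) {
    abort(sprintf("Reference channel '%s' not in schedule.",
                  reference_channel),
          class = "gliatrace_data_error")
  }
  prep <- function(ch) detrend_bleach(smooth_trace(traces[[ch]], smooth_window))
  ref <- prep(reference_channel)

  results <- list(traces = dplyr::bind_rows(traces))
  metrics <- list()
  log <- log_row("photometry", "demultiplex", nrow(stream),
                 sum(vapply(traces, nrow, integer(1))))
  for (ch in setdiff(names(traces), reference_channel)) {
    dff <- compute_dff(prep(ch), ref, baseline_window_s)
    window <- range(dff$time_s)
    m <- transient_metrics(dff, window)
    m$channel_id <- ch
    metrics[[ch]] <- m
    results[[paste0("dff_", ch)]] <- dff
    if (!is.null(ca_channel) && ch == ca_channel) {
      filtered <- bandpass_filter(dff)
      ev <- detect_events(filtered, event_params(
        quiescent_windows_s = list(baseline_window_s)))
      results$events <- ev
      results$event_stats <- event_stats(ev)
      log <- dplyr::bind_rows(log, log_row("photometry", "detect_events",
                                           nrow(filtered), nrow(ev)))
    }
  }
  results$metrics <- dplyr::bind_rows(metrics)
  write_report(results, out_dir)
  write_table(log, file.path(out_dir, "run_log.csv"))
  invisible(log)
}

#' Run the region screen on count, group and ontology files
#'
#' Joins counts to groups, converts to densities, excludes
#' ventricular-niche and aggregate regions, runs the Levene-routed
#' screen, and writes the report plus reference-group fold changes.
#'
#' @param counts_path Count CSV (`region_id`, `subject_id`, `count`).
#' @param ontology_path Ontology JSON.
#' @param groups_path Subject-group CSV (`subject_id`, `group`).
#' @param out_dir Output directory.
#' @param alpha FDR level.
#' @param reference_group Fold-change reference group.
#' @return Invisibly, the run-log tibble.
#' @export
run_screen <- function(counts_path, ontology_path, groups_path, out_dir,
                       alpha = 0.05, reference_group = "NoFC") {
  counts <- load_table(counts_path, "counts")
  subjects <- load_table(groups_path, "subjects")
  ontology <- read_ontology(ontology_path)
  unmapped <- setdiff(unique(counts$subject_id), subjects$subject_id)
  if (length(unmapped)) {
    abort(sprintf("Subjects without a group: %s",
                  paste(head(unmapped, 5), collapse = ", ")),
          class = "gliatrace_data_error")
  }
  counts$group <- subjects$group[match(counts$subject_id, subjects$subject_id)]

  density <- make_density(counts, ontology)
  kept <- filter_regions(density, ontology)
  excl <- attr(kept, "exclusion_log")
  screen <- screen_regions(kept, alpha = alpha)
  fc <- fold_changes(kept, reference_group = reference_group)
  sig <- screen |>
    dplyr::filter(.data$significant) |>
    dplyr::distinct(.data$region_id)

  write_report(list(screen = screen, fold_changes = fc,
                    excluded_regions = excl,
                    skipped_regions = attr(screen, "skipped"),
                    significant_regions = sig), out_dir)
  log <- dplyr::bind_rows(
    log_row("screen", "filter_regions", nrow(density), nrow(kept)),
    log_row("screen", "screen_regions", dplyr::n_distinct(kept$region_id),
            dplyr::n_distinct(screen$region_id))
  )
  write_table(log, file.path(out_dir, "run_log.csv"))
  invisible(log)
}

#' Run the single-cell quantification on a cell-table file
#'
#' Marker normalization, within-sample z-scoring, high/low
#' classification at the default cut-offs, the receptor co-expression
#' index against the reference condition, and the Fos-Adrb1 and
#' Adrb1-Igfbp2 z-score correlations.
#'
#' @param in_path Cell CSV (`cell_id`, `sample_id`, `condition`, one
#'   column per gene).
#' @param out_dir Output directory.
#' @param reference_condition Reference condition for the co-expression
#'   index.
#' @return Invisibly, the run-log tibble.
#' @export
run_cells <- function(in_path, out_dir, reference_condition = "NoFC") {
  cells <- load_table(in_path, "cells")
  stats <- normalize_by_marker(cells)
  excl <- attr(stats, "exclusion_log")
  stats <- zscore_by_sample(stats)
  stats <- classify_high(stats)
  ci <- coexpression_index(stats, reference_condition = reference_condition)
  cors <- dplyr::bind_rows(
    dplyr::mutate(gene_correlation(stats, "Fos", "Adrb1"),
                  pair = "Fos-Adrb1"),
    dplyr::mutate(gene_correlation(stats, "Adrb1", "Igfbp2"),
                  pair = "Adrb1-Igfbp2")
  )
  write_report(list(cell_stats = stats,
                    label_counts = attr(stats, "label_counts"),
                    coexpression_index = ci,
                    coexpression_summary = attr(ci, "summary"),
                    correlations = cors,
                    excluded_cells = excl), out_dir)
  log <- log_row("cells", "normalize_by_marker", nrow(cells),
                 dplyr::n_distinct(stats$cell_id))
  write_table(log, file.path(out_dir, "run_log.csv"))
  invisible(log)
}

# ---- command-line interface ------------------------------------------------

cli_usage <- function(cmd = NULL) {
  general <- paste(
    "usage: gliatrace <simulate|photometry|screen|cells|all> [options]",
    "",
    "subcommands:",
    "  simulate    --out DIR [--seed N] [--preset null|effect]",
    "  photometry  --in STREAM.csv --out DIR [--baseline START,END]",
    "  screen      --counts F --ontology F --groups F --out DIR [--alpha A]",
    "  cells       --in CELLS.csv --out DIR [--reference COND]",
    "  all         --out DIR [--seed N] [--preset null|effect]",
    "",
    "`--help` on any subcommand prints this message.",
    sep = "\n")
  general
}

parse_cli <- function(argv) {
  opts <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--help") {
      opts$help <- TRUE
      i <- i + 1
    } else if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(argv) || grepl("^--", argv[i + 1])) {
        abort(sprintf("Flag --%s needs a value.", key),
              class = "gliatrace_user_error")
      }
      opts[[key]] <- argv[i + 1]
      i <- i + 2
    } else {
      abort(sprintf("Unexpected argument '%s'.", a),
            class = "gliatrace_user_error")
    }
  }
  opts
}

require_opt <- function(opts, key) {
  if (is.null(opts[[key]])) {
    abort(sprintf("Missing required flag --%s.", key),
          class = "gliatrace_user_error")
  }
  opts[[key]]
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands. Exit status 0 on success, 1 on a
#' usage error (unknown subcommand, missing flags), 2 on a data error
#' (malformed input files). All randomness derives from `--seed`, so
#' `gliatrace(c("all", "--seed", "0", "--out", d))` is fully
#' reproducible: two runs produce byte-identical reports.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
gliatrace <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(argv) || argv[1] %in% c("--help", "help")) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    cmd <- argv[1]
    if (!cmd %in% c("simulate", "photometry", "screen", "cells", "all")) {
      abort(sprintf("Unknown subcommand '%s'.", cmd),
            class = "gliatrace_user_error")
    }
    opts <- parse_cli(argv[-1])
    if (isTRUE(opts$help)) {
      cat(cli_usage(cmd), "\n")
      return(invisible(0L))
    }
    seed <- as.integer(opts$seed %||% 0)
    preset <- opts$preset %||% "null"
    switch(cmd,
      simulate = run_simulate(require_opt(opts, "out"), seed, preset),
      photometry = {
        baseline <- as.numeric(strsplit(opts$baseline %||% "0,60", ",")[[1]])
        run_photometry(require_opt(opts, "in"), require_opt(opts, "out"),
                       baseline_window_s = baseline)
      },
      screen = run_screen(require_opt(opts, "counts"),
                          require_opt(opts, "ontology"),
                          require_opt(opts, "groups"),
                          require_opt(opts, "out"),
                          alpha = as.numeric(opts$alpha %||% 0.05)),
      cells = run_cells(require_opt(opts, "in"), require_opt(opts, "out"),
                        reference_condition = opts$reference %||% "NoFC"),
      all = {
        out <- require_opt(opts, "out")
        run_simulate(file.path(out, "simulate"), seed, preset)
        run_photometry(file.path(out, "simulate", "stream.csv"),
                       file.path(out, "photometry"),
                       baseline_window_s = c(0, 60))
        run_screen(file.path(out, "simulate", "region_counts.csv"),
                   file.path(out, "simulate", "ontology.json"),
                   file.path(out, "simulate", "subjects.csv"),
                   file.path(out, "screen"))
        run_cells(file.path(out, "simulate", "cell_table.csv"),
                  file.path(out, "cells"))
      }
    )
    0L
  },
  gliatrace_user_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
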