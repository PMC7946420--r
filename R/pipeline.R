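# Study orchestration: generate -> analyze -> report, with per-stage
# derived seeds and persisted intermediate tables.

# Stable per-stage seed derived from the master seed and the stage name, so
# stages can be re-run in isolation reproducibly. Kept below 2^31.
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 2654435761 + h) %% .Machine$integer.max)
}

#' Run a complete simulated study
#'
#' Executes the three stages in order -- `generate` (synthetic session),
#' `analyze` (per-neuron summaries, population correlations, firing-mode
#' bootstrap on the flagged tonic increasers) and optionally `report`
#' (figures and a markdown summary) -- persisting every intermediate table
#' under `out_dir`. Identical config and seed give identical CSVs. No
#' analysis stage reads the ground-truth table.
#'
#' @param config A `study_config` (see [read_study_config()]).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory.
#' @param report Also emit figures and `report.md`.
#' @return List of class `"study_report"` with the summary tables and
#'   per-stage exclusion counts.
#' @export
run_study <- function(config = read_study_config(), seed = 1L,
                      out_dir = tempfile("study"), report = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  # -- generate ------------------------------------------------------------
  session <- simulate_population(
    config$task, counts = config$population, n_blocks = config$n_blocks,
    seed = derive_seed(seed, "generate"))
  write_session(session, file.path(out_dir, "session"), seed = seed)
  log$n_trials <- nrow(session$trials)
  log$n_aborted <- sum(session$trials$aborted)
  log$n_neurons <- length(unique(session$spikes$neuron_id))

  # -- analyze -------------------------------------------------------------
  summary <- suppressMessages(
    summarize_population(session, config$windows))
  utils::write.csv(summary, file.path(out_dir, "neuron_summary.csv"),
                   row.names = FALSE)
  correlations <- population_correlations(summary)
  utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  inc_ids <- summary$neuron_id[!is.na(summary$tonic_increaser) &
                                 summary$tonic_increaser]
  log$n_tonic_increasers <- length(inc_ids)
  log$n_tonic_decreasers <- sum(summary$tonic_decreaser, na.rm = TRUE)
  log$n_unusable_slope <- sum(is.na(summary$slope_increase))
  boot <- NULL
  if (length(inc_ids) >= 2) {
    deltas <- suppressMessages(
      mode_period_deltas(session, inc_ids, "value_increase",
                         config$windows, config$burst))
    boot <- bootstrap_mode_comparison(deltas, config$bootstrap,
                                      seed = derive_seed(seed, "bootstrap"))
    utils::write.csv(boot, file.path(out_dir, "bootstrap.csv"),
                     row.names = FALSE)
  }

  rep_obj <- structure(list(summary = summary, correlations = correlations,
                            bootstrap = boot, log = log,
                            out_dir = out_dir, seed = seed),
                       class = "study_report")
  # -- report --------------------------------------------------------------
  if (report) write_report(rep_obj, session, config)
  rep_obj
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed", x$seed, "\n")
  cat(sprintf(
    " neurons: %d | tonic increasers: %d | tonic decreasers: %d\n",
    x$log$n_neurons, x$log$n_tonic_increasers, x$log$n_tonic_decreasers))
  cat(sprintf(" cue value coders: %d | trials: %d (aborted %d)\n",
              sum(x$summary$cue_value_coder, na.rm = TRUE),
              x$log$n_trials, x$log$n_aborted))
  if (!is.null(x$bootstrap)) {
    cat(" firing-mode bootstrap:\n")
    print(x$bootstrap[, c("period", "count_non_burst_larger",
                          "count_burst_larger", "significant")])
  }
  invisible(x)
}

write_report <- function(rep_obj, session, config) {
  out_dir <- rep_obj$out_dir
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  s <- rep_obj$summary
  # figures are regenerable artifacts; a failing graphics device must not
  # abort the report stage
  tryCatch(write_report_figures(s, session, config, fig_dir),
           error = function(e)
             message("figure generation skipped: ", conditionMessage(e)))
  lines <- c(
    "# Study report", "",
    sprintf("- neurons analysed: %d", rep_obj$log$n_neurons),
    sprintf("- significant tonic increasers: %d",
            rep_obj$log$n_tonic_increasers),
    sprintf("- significant tonic decreasers: %d",
            rep_obj$log$n_tonic_decreasers),
    sprintf("- cue value coders: %d",
            sum(s$cue_value_coder, na.rm = TRUE)),
    "", "## Tonic-phasic correlations", "",
    utils::capture.output(print(rep_obj$correlations)))
  if (!is.null(rep_obj$bootstrap))
    lines <- c(lines, "", "## Firing-mode bootstrap", "",
               utils::capture.output(print(rep_obj$bootstrap)))
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

write_report_figures <- function(s, session, config, fig_dir) {
  grDevices::png(file.path(fig_dir, "slope_histograms.png"), 900, 400)
  graphics::par(mfrow = c(1, 2))
  graphics::hist(s$slope_increase, breaks = 20, main = "value-increase",
                 xlab = "slope (spikes/s per s)")
  graphics::hist(s$slope_decrease, breaks = 20, main = "value-decrease",
                 xlab = "slope (spikes/s per s)")
  grDevices::dev.off()
  grDevices::png(file.path(fig_dir, "tonic_vs_phasic.png"), 450, 450)
  graphics::plot(s$slope_increase, s$cue_coef,
                 xlab = "tonic slope, value-increase (spikes/s per s)",
                 ylab = "cue coefficient (spikes/s per level)")
  grDevices::dev.off()
  inc_ids <- s$neuron_id[!is.na(s$tonic_increaser) & s$tonic_increaser]
  if (length(inc_ids) >= 1) {
    grid <- seq(0, 2450, by = 10)
    acc <- NULL
    for (nid in inc_ids) {
      al <- suppressMessages(align_spikes(session, nid, "cs_onset",
                                          conditions = "value_increase"))
      tru <- truncate_at_stop(al, session$trials)
      sdf <- compute_sdf(tru, grid = grid)
      sdf <- subtract_baseline(sdf, baseline_rate(session, nid,
                                                  config$windows))
      acc <- if (is.null(acc)) sdf$rate else acc + sdf$rate
    }
    grDevices::png(file.path(fig_dir, "population_sdf_increase.png"),
                   700, 400)
    graphics::plot(grid, acc / length(inc_ids), type = "l",
                   xlab = "time from CS onset (ms)",
                   ylab = "rate - baseline (spikes/s)",
                   main = "tonic increasers, value-increase")
    grDevices::dev.off()
  }
  invisible(fig_dir)
}

#' Command-line entry point
#'
#' Verbs: `generate` (config -> synthetic session CSVs), `analyze` (session
#' CSVs -> summary/bootstrap CSVs), `report` (adds figures and report.md),
#' `run` (all three). Flags: `--config PATH`, `--seed INT`, `--out DIR`.
#' Install target: `Rscript -e 'valueramp::vr_cli()' run --seed 1 --out d`
#' or the `inst/cli/valueramp` launcher.
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status, invisibly.
#' @export
vr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: valueramp <generate|analyze|report|run>",
    "[--config PATH] [--seed INT] [--out DIR] [--session DIR]")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  verb <- args[1]
  opt <- list(config = NULL, seed = 1L, out = "valueramp_out",
              session = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown flag: ", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  opt$seed <- as.integer(opt$seed)
  cfg <- read_study_config(opt$config)
  switch(verb,
    generate = {
      session <- simulate_population(cfg$task, counts = cfg$population,
                                     n_blocks = cfg$n_blocks,
                                     seed = derive_seed(opt$seed, "generate"))
      write_session(session, file.path(opt$out, "session"), seed = opt$seed)
      message("session written to ", file.path(opt$out, "session"))
    },
    analyze = {
      sdir <- opt$session %||% file.path(opt$out, "session")
      session <- load_session(sdir, config = cfg$task)
      summary <- summarize_population(session, cfg$windows)
      utils::write.csv(summary, file.path(opt$out, "neuron_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(population_correlations(summary),
                       file.path(opt$out, "correlations.csv"),
                       row.names = FALSE)
      message("analysis written to ", opt$out)
    },
    report = ,
    run = {
      rep_obj <- run_study(cfg, seed = opt$seed, out_dir = opt$out,
                           report = verb == "report")
      print(rep_obj)
    },
    stop("unknown verb '", verb, "'\n", usage))
  invisible(0L)
}
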