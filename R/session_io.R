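# CSV serialization of sessions and JSON study configs.

vr_trial_csv_cols <- c("session_id", "trial_id", "block_index", "condition",
                       "cs_type", "stop_time_ms", "reward_ml",
                       "fixation_onset_ms", "cs_onset_ms", "reward_onset_ms",
                       "aborted")

#' Write a session to a directory of CSV files
#'
#' Emits `trials.csv`, `spikes.csv` and, when present, `gaze.csv`,
#' `licks.csv`, `ground_truth.csv` and `spike_provenance.csv` (debug table),
#' plus a `manifest.json` listing the members, the generating seed (if
#' known) and a hash of the task configuration.
#'
#' @param session A [session_data()].
#' @param dir Output directory (created if needed).
#' @param seed Optional seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- session$trials
  tr$session_id <- session$session_id
  utils::write.csv(tr[, vr_trial_csv_cols], file.path(dir, "trials.csv"),
                   row.names = FALSE)
  sp <- session$spikes
  sp <- cbind(session_id = session$session_id, sp)
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  members <- c("trials.csv", "spikes.csv")
  for (part in c("gaze", "licks", "ground_truth", "provenance")) {
    tab <- session[[part]]
    if (is.null(tab)) next
    fn <- if (part == "provenance") "spike_provenance.csv"
    else paste0(part, ".csv")
    utils::write.csv(tab, file.path(dir, fn), row.names = FALSE)
    members <- c(members, fn)
  }
  manifest <- list(session_id = session$session_id, members = members,
                   seed = seed,
                   config_hash = vr_config_hash(session$config),
                   config = unclass(session$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

# Cheap deterministic hash of a config list (sum over serialized bytes).
vr_config_hash <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% 2^31)
}

#' Load a session from a directory of CSV files
#'
#' Validates the schema and referential integrity (see [session_data()]);
#' gaze/lick/ground-truth files are optional, and their absence simply
#' disables the corresponding analyses.
#'
#' @param dir Directory written by [write_session()] (or conforming files).
#' @param config Optional [task_config()]; defaults to the one recorded in
#'   `manifest.json` when present, else the package default.
#' @return A [session_data()].
#' @export
load_session <- function(dir, config = NULL) {
  need <- file.path(dir, c("trials.csv", "spikes.csv"))
  if (!all(file.exists(need)))
    stop("session directory must contain trials.csv and spikes.csv")
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  miss <- setdiff(vr_trial_csv_cols, names(trials))
  if (length(miss))
    stop("trials.csv missing columns: ", paste(miss, collapse = ", "))
  trials$stop_onset_ms <- trials$cs_onset_ms + trials$stop_time_ms
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  smiss <- setdiff(c("neuron_id", "trial_id", "spike_time_ms"),
                   names(spikes))
  if (length(smiss))
    stop("spikes.csv missing columns: ", paste(smiss, collapse = ", "))
  opt <- function(fn) {
    p <- file.path(dir, fn)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  if (is.null(config)) {
    mf <- file.path(dir, "manifest.json")
    config <- if (file.exists(mf)) {
      raw <- jsonlite::read_json(mf, simplifyVector = TRUE)$config
      raw$quantize_stop_ms <- raw$quantize_stop_ms %||% NULL
      do.call(task_config, raw[!vapply(raw, is.null, logical(1))])
    } else task_config()
  }
  gaze <- opt("gaze.csv")
  if (is.null(gaze)) message("gaze.csv absent: gaze analyses disabled")
  session_data(trials = trials,
               spikes = spikes[, c("neuron_id", "trial_id", "spike_time_ms")],
               gaze = gaze, licks = opt("licks.csv"),
               ground_truth = opt("ground_truth.csv"),
               provenance = opt("spike_provenance.csv"),
               config = config,
               session_id = as.character(trials$session_id[1]))
}

#' Read a study configuration from JSON
#'
#' The file may contain `task`, `windows`, `burst`, `bootstrap`,
#' `population`, and `n_blocks` sections; omitted sections fall back to
#' package defaults.
#'
#' @param path JSON file, or `NULL` for all defaults.
#' @return List of class `"study_config"`.
#' @export
read_study_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
  else jsonlite::read_json(path, simplifyVector = TRUE)
  task <- if (!is.null(raw$task))
    do.call(task_config, raw$task) else task_config()
  windows <- if (!is.null(raw$windows)) {
    w <- raw$windows
    if (!is.null(w$periods)) w$periods <- as.matrix(w$periods)
    if (!is.null(w$value_groups)) w$value_groups <- as.matrix(w$value_groups)
    do.call(analysis_windows, w)
  } else analysis_windows()
  burst <- if (!is.null(raw$burst))
    do.call(burst_criteria, raw$burst) else burst_criteria()
  boot <- if (!is.null(raw$bootstrap))
    do.call(bootstrap_config, raw$bootstrap) else bootstrap_config()
  pop <- raw$population %||% c(tonic_increaser = 19, tonic_decreaser = 15,
                               phasic_only = 30, null = 35)
  structure(list(task = task, windows = windows, burst = burst,
                 bootstrap = boot, population = unlist(pop),
                 n_blocks = raw$n_blocks %||% 1L),
            class = "study_config")
}
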