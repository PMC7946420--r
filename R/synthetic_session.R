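# Session-level synthetic data: neuron populations, gaze traces, lick
# events and choice-task behaviour, bundled in a session_data container.

#' Session container: trials, spikes and optional behaviour tables
#'
#' @param trials Trial table (see [sample_trial()] for columns).
#' @param spikes Spike table with `neuron_id`, `trial_id`, `spike_time_ms`.
#' @param gaze,licks Optional gaze / lick tables.
#' @param ground_truth Optional `data.frame` of generator parameters (one
#'   row per neuron); absent for loaded real-format data.
#' @param provenance Optional debug table of per-spike source tags; only
#'   white-box tests may read it.
#' @param config The [task_config()] used.
#' @param session_id Identifier stamped on export.
#' @return List of class `"session_data"`.
#' @export
session_data <- function(trials, spikes, gaze = NULL, licks = NULL,
                         ground_truth = NULL, provenance = NULL,
                         config = task_config(), session_id = "S1") {
  obj <- structure(list(trials = trials, spikes = spikes, gaze = gaze,
                        licks = licks, ground_truth = ground_truth,
                        provenance = provenance, config = config,
                        session_id = session_id),
                   class = "session_data")
  validate_session_data(obj)
  obj
}

validate_session_data <- function(x) {
  need <- c("trial_id", "condition", "cs_type", "stop_time_ms", "reward_ml",
            "fixation_onset_ms", "cs_onset_ms", "reward_onset_ms", "aborted")
  miss <- setdiff(need, names(x$trials))
  if (length(miss))
    stop("trial table missing columns: ", paste(miss, collapse = ", "))
  sneed <- c("neuron_id", "trial_id", "spike_time_ms")
  miss <- setdiff(sneed, names(x$spikes))
  if (length(miss))
    stop("spike table missing columns: ", paste(miss, collapse = ", "))
  orphan <- !(x$spikes$trial_id %in% x$trials$trial_id)
  if (any(orphan))
    stop("spike rows reference unknown trial_ids (first offending row: ",
         which(orphan)[1], ")")
  tr <- x$trials[match(x$spikes$trial_id, x$trials$trial_id), ]
  bad <- x$spikes$spike_time_ms < 0 |
    x$spikes$spike_time_ms > tr$reward_onset_ms + 500
  if (any(bad))
    stop("spike times outside [0, reward_onset + 500] (first offending row: ",
         which(bad)[1], ")")
  if (!is.null(x$gaze)) {
    gneed <- c("trial_id", "sample_time_ms", "x_deg", "y_deg")
    miss <- setdiff(gneed, names(x$gaze))
    if (length(miss))
      stop("gaze table missing columns: ", paste(miss, collapse = ", "))
    dup <- duplicated(x$gaze[, c("trial_id", "sample_time_ms")])
    if (any(dup)) stop("duplicate gaze timestamps within a trial")
  }
  invisible(x)
}

#' @export
print.session_data <- function(x, ...) {
  cat("<session_data>", x$session_id, "\n",
      " trials: ", nrow(x$trials),
      " | neurons: ", length(unique(x$spikes$neuron_id)),
      " | spikes: ", nrow(x$spikes), "\n",
      " gaze: ", if (is.null(x$gaze)) "absent" else nrow(x$gaze),
      " | licks: ", if (is.null(x$licks)) "absent" else nrow(x$licks),
      " | ground truth: ", if (is.null(x$ground_truth)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' Draw ground-truth neurons for the standard population classes
#'
#' Classes mirror the functional groups the analysis is meant to separate:
#' `tonic_increaser` (positive tonic coupling in the value-increase
#' condition, non-burst-dominant firing), `tonic_decreaser` (coupling in
#' the value-decrease condition), `phasic_only` (CS- and stop-locked burst
#' responses, no tonic term) and `null` (stationary). Baselines are drawn
#' uniform on 3--5 spikes/s; tonic gains uniform on 10--18 spikes/s per ml;
#' phasic gains uniform on 1--3 spikes/s per value level.
#'
#' @param counts Named integer vector of class counts, e.g.
#'   `c(tonic_increaser = 19, tonic_decreaser = 15, phasic_only = 30,
#'   null = 35)`.
#' @param first_id Id of the first neuron.
#' @return List of [neuron_ground_truth()] objects.
#' @export
draw_population <- function(counts, first_id = 1L) {
  stopifnot(all(counts >= 0),
            all(names(counts) %in% c("tonic_increaser", "tonic_decreaser",
                                     "phasic_only", "null")))
  neurons <- list()
  id <- as.integer(first_id)
  for (cls in names(counts)) {
    for (i in seq_len(counts[[cls]])) {
      base <- stats::runif(1, 3, 5)
      n <- switch(cls,
        tonic_increaser = neuron_ground_truth(
          neuron_id = id, baseline_rate = base,
          tonic_gain_increase = stats::runif(1, 10, 18),
          cs_phasic_gain = stats::runif(1, 1, 3),
          stop_phasic_gain = stats::runif(1, 1, 3),
          tonic_mode = "non_burst_dominant"),
        tonic_decreaser = neuron_ground_truth(
          neuron_id = id, baseline_rate = base,
          tonic_gain_decrease = stats::runif(1, 10, 18),
          cs_phasic_gain = stats::runif(1, 1, 3),
          stop_phasic_gain = stats::runif(1, 1, 3),
          tonic_mode = "non_burst_dominant"),
        phasic_only = neuron_ground_truth(
          neuron_id = id, baseline_rate = base,
          cs_phasic_gain = stats::runif(1, 1, 3),
          stop_phasic_gain = stats::runif(1, 1, 3),
          tonic_mode = "mixed"),
        null = neuron_ground_truth(
          neuron_id = id, baseline_rate = base, tonic_mode = "mixed"))
      n$class <- cls
      neurons[[length(neurons) + 1L]] <- n
      id <- id + 1L
    }
  }
  neurons
}

ground_truth_table <- function(neurons) {
  data.table::rbindlist(lapply(neurons, function(n) data.frame(
    neuron_id = n$neuron_id, class = n$class %||% NA_character_,
    baseline_rate = n$baseline_rate,
    tonic_gain_increase = n$tonic_gain_increase,
    tonic_gain_decrease = n$tonic_gain_decrease,
    cs_phasic_gain = n$cs_phasic_gain,
    stop_phasic_gain = n$stop_phasic_gain,
    burst_fraction = n$burst_fraction, tonic_mode = n$tonic_mode))) |>
    as.data.frame()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full recording session
#'
#' Builds trials in the configured block order (repeated `n_blocks` times),
#' simulates every neuron on every non-aborted trial, and optionally adds
#' gaze and lick tables. Identical seeds produce identical sessions.
#'
#' @param config A [task_config()].
#' @param counts Population class counts (see [draw_population()]), or a
#'   list of [neuron_ground_truth()] objects via `neurons`.
#' @param n_blocks Blocks per condition.
#' @param neurons Optional explicit neuron list (overrides `counts`).
#' @param seed Optional integer seed (sets the global RNG).
#' @param gaze,licks Logical: attach simulated gaze / lick tables.
#' @param session_id Session identifier.
#' @return A [session_data()] with `ground_truth` and `provenance` attached.
#' @export
simulate_population <- function(config = task_config(),
                                counts = c(tonic_increaser = 19,
                                           tonic_decreaser = 15,
                                           phasic_only = 30, null = 35),
                                n_blocks = 1L, neurons = NULL, seed = NULL,
                                gaze = FALSE, licks = FALSE,
                                session_id = "S1") {
  if (!is.null(seed)) set.seed(seed)
  if (n_blocks < 1L) stop("need at least one block per condition")
  if (is.null(neurons)) neurons <- draw_population(counts)

  blocks <- list(); tid <- 1L; bidx <- 1L
  for (rep_i in seq_len(n_blocks)) {
    for (cond in config$block_order) {
      blocks[[length(blocks) + 1L]] <-
        sample_block(config, cond, block_index = bidx, first_trial_id = tid)
      tid <- tid + config$block_size; bidx <- bidx + 1L
    }
  }
  trials <- as.data.frame(data.table::rbindlist(blocks))

  live <- trials[trials$aborted == 0L, ]
  live_rows <- lapply(seq_len(nrow(live)), function(i) as.list(live[i, ]))
  sp_t <- vector("list", nrow(live) * max(length(neurons), 1L))
  sp_meta <- sp_t
  slot <- 1L
  for (n in neurons) {
    for (i in seq_along(live_rows)) {
      tr <- live_rows[[i]]
      st <- simulate_trial_spikes(n, tr, config)
      if (length(st)) {
        sp_t[[slot]] <- st
        sp_meta[[slot]] <- list(n$neuron_id, tr$trial_id, attr(st, "source"))
      }
      slot <- slot + 1L
    }
  }
  keep <- !vapply(sp_t, is.null, logical(1))
  sp_t <- sp_t[keep]; sp_meta <- sp_meta[keep]
  nsp <- vapply(sp_t, length, integer(1))
  spikes <- data.frame(
    neuron_id = rep(vapply(sp_meta, `[[`, integer(1), 1L), nsp),
    trial_id = rep(vapply(sp_meta, `[[`, integer(1), 2L), nsp),
    spike_time_ms = as.numeric(unlist(sp_t)))
  provenance <- cbind(spikes,
                      source = unlist(lapply(sp_meta, `[[`, 3L)))

  gaze_tab <- NULL
  if (isTRUE(gaze)) {
    gz <- lapply(seq_len(nrow(live)), function(i) {
      tr <- live[i, ]
      n_sac <- stats::rpois(1, 2)
      onsets <- sort(stats::runif(n_sac, tr$cs_onset_ms + 100,
                                  tr$reward_onset_ms - 200))
      sched <- data.frame(onset_ms = onsets,
                          amplitude_deg = stats::runif(n_sac, 3, 7),
                          duration_ms = stats::runif(n_sac, 35, 50))
      cbind(trial_id = tr$trial_id, simulate_gaze(tr, sched))
    })
    gaze_tab <- as.data.frame(data.table::rbindlist(gz))
  }
  lick_tab <- NULL
  if (isTRUE(licks)) {
    lk <- lapply(seq_len(nrow(live)), function(i) {
      tr <- live[i, ]
      on <- simulate_licks(tr, rate_hz = 1)
      if (!length(on)) return(NULL)
      data.frame(trial_id = tr$trial_id, lick_onset_ms = on)
    })
    lk <- lk[!vapply(lk, is.null, logical(1))]
    lick_tab <- if (length(lk)) as.data.frame(data.table::rbindlist(lk))
  }

  session_data(trials = trials, spikes = spikes, gaze = gaze_tab,
               licks = lick_tab, ground_truth = ground_truth_table(neurons),
               provenance = provenance, config = config,
               session_id = session_id)
}

#' Simulate a 240 Hz gaze trace with injected saccades
#'
#' Fixation noise is Gaussian positional jitter (SD `noise_sd` degrees);
#' each scheduled saccade is a minimum-jerk displacement along the vertical
#' axis (the bar stimulus is vertical), giving an unambiguous velocity
#' threshold crossing. Injected onsets are the ground truth for detector
#' round-trip tests.
#'
#' @param trial One trial record.
#' @param saccades `data.frame` with `onset_ms`, `amplitude_deg`,
#'   `duration_ms` (may have zero rows).
#' @param rate_hz Sampling rate, default 240.
#' @param noise_sd Positional jitter SD, degrees.
#' @return `data.frame` with `sample_time_ms`, `x_deg`, `y_deg`.
#' @export
simulate_gaze <- function(trial, saccades = NULL, rate_hz = 240,
                          noise_sd = 0.2) {
  t_end <- trial$reward_onset_ms + 500
  tt <- seq(0, t_end, by = 1000 / rate_hz)
  if (!is.null(saccades) && nrow(saccades)) {
    if (any(saccades$onset_ms < 0 |
              saccades$onset_ms + saccades$duration_ms > t_end))
      stop("saccade onsets/offsets outside the trial")
  }
  y <- numeric(length(tt))
  if (!is.null(saccades) && nrow(saccades)) {
    for (i in seq_len(nrow(saccades))) {
      tau <- (tt - saccades$onset_ms[i]) / saccades$duration_ms[i]
      tau <- pmin(pmax(tau, 0), 1)
      # minimum-jerk position profile
      y <- y + saccades$amplitude_deg[i] *
        (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
    }
  }
  data.frame(sample_time_ms = tt,
             x_deg = stats::rnorm(length(tt), 0, noise_sd),
             y_deg = y + stats::rnorm(length(tt), 0, noise_sd))
}

#' Simulate lick onsets as a Poisson process
#'
#' By default the lick process is independent of neural firing, so
#' lick-aligned spike density functions of simulated neurons are flat by
#' construction (an independence null for the lick control analysis).
#'
#' @param trial One trial record.
#' @param rate_hz Lick rate, events/s (scalar, homogeneous) over the CS
#'   period.
#' @param window_ms Interval (within-trial ms) on which licks occur;
#'   defaults to the CS period.
#' @return Numeric vector of lick onset times (ms).
#' @export
simulate_licks <- function(trial, rate_hz = 1, window_ms = NULL) {
  if (is.null(window_ms))
    window_ms <- c(trial$cs_onset_ms, trial$reward_onset_ms)
  len_s <- (window_ms[2] - window_ms[1]) / 1000
  if (rate_hz <= 0 || len_s <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_hz * len_s)
  sort(stats::runif(n, window_ms[1], window_ms[2]))
}

#' Simulate choice-task sessions under a logistic value rule
#'
#' Each trial assigns independent uniform values on
#' `uncertain_reward_interval` to the right and left stimuli and draws the
#' choice of the right stimulus as Bernoulli with
#' `P = 1 / (1 + exp(-(beta0 + beta1 * (v_right - v_left))))`.
#'
#' @param config A [task_config()].
#' @param beta0,beta1 Logistic intercept and value-difference slope (per
#'   ml).
#' @param n_trials Number of choice trials.
#' @return `data.frame` with `v_right`, `v_left`, `choice_right`.
#' @export
simulate_choice_sessions <- function(config = task_config(), beta0 = 0,
                                     beta1 = 10, n_trials = 500) {
  if (!is.finite(beta0) || !is.finite(beta1))
    stop("beta0 and beta1 must be finite")
  iv <- config$uncertain_reward_interval
  vr <- stats::runif(n_trials, iv[1], iv[2])
  vl <- stats::runif(n_trials, iv[1], iv[2])
  p <- 1 / (1 + exp(-(beta0 + beta1 * (vr - vl))))
  data.frame(v_right = vr, v_left = vl,
             choice_right = as.integer(stats::runif(n_trials) < p))
}
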