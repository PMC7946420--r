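# Signal-level operations: event alignment, stop truncation, Gaussian-kernel
# spike density functions, baseline and binned firing rates, saccade
# detection.

#' Analysis windows and binning constants
#'
#' All measurement windows used by the analyses, in ms relative to their
#' alignment event: 500--0 ms before fixation onset for baselines; nine
#' 200 ms bins over 650--2450 ms after CS onset for the tonic slope;
#' 100--400 ms after CS onset for the cue response; 150--500 ms after the
#' ramp stop for the stop response; initial/middle/late 600 ms periods
#' tiling the slope window; and the three reward-value groups (small
#' 0.1--0.16, medium 0.16--0.23, large 0.23--0.3 ml). Intervals are
#' half-open `[start, end)` except the final bin/group, which is closed at
#' the global maximum.
#'
#' @param baseline,tonic_fit,cue_response,stop_response Interval bounds, ms.
#' @param tonic_bin Bin width for the tonic fit, ms.
#' @param periods 3x2 matrix of period bounds, ms after CS onset.
#' @param value_groups 3x2 matrix of value-group bounds, ml (rows small,
#'   medium, large).
#' @return List of class `"analysis_windows"`.
#' @export
analysis_windows <- function(baseline = c(-500, 0),
                             tonic_fit = c(650, 2450),
                             tonic_bin = 200,
                             cue_response = c(100, 400),
                             stop_response = c(150, 500),
                             periods = rbind(initial = c(650, 1250),
                                             middle = c(1250, 1850),
                                             late = c(1850, 2450)),
                             value_groups = rbind(small = c(0.1, 0.16),
                                                  medium = c(0.16, 0.23),
                                                  large = c(0.23, 0.3))) {
  w <- list(baseline = baseline, tonic_fit = tonic_fit,
            tonic_bin = tonic_bin, cue_response = cue_response,
            stop_response = stop_response, periods = periods,
            value_groups = value_groups)
  nb <- (tonic_fit[2] - tonic_fit[1]) / tonic_bin
  if (abs(nb - round(nb)) > 1e-9)
    stop("tonic_fit length must be divisible by tonic_bin")
  if (periods[1, 1] != tonic_fit[1] || periods[nrow(periods), 2] !=
        tonic_fit[2] || any(periods[-1, 1] != periods[-nrow(periods), 2]))
    stop("periods must tile the tonic_fit window exactly")
  if (any(value_groups[-1, 1] != value_groups[-nrow(value_groups), 2]))
    stop("value_groups must tile the value range with no overlap")
  structure(w, class = "analysis_windows")
}

vr_event_column <- function(event) {
  switch(event,
         fixation_onset = "fixation_onset_ms",
         cs_onset = "cs_onset_ms",
         stop_onset = "stop_onset_ms",
         reward_onset = "reward_onset_ms",
         stop("unknown alignment event '", event, "'"))
}

#' Align one neuron's spikes to a trial event
#'
#' Subtracts the event timestamp from each spike time, per trial. Aborted
#' trials are excluded; trials lacking the event (e.g. stop alignment on
#' value-fixed trials) are skipped and counted.
#'
#' @param session A [session_data()].
#' @param neuron_id Neuron to align.
#' @param event One of `"fixation_onset"`, `"cs_onset"`, `"stop_onset"`,
#'   `"reward_onset"`.
#' @param conditions Optional condition filter.
#' @param cs_types Optional CS-type filter.
#' @return `data.frame` with `trial_id`, `t_rel` (ms relative to the
#'   event); attributes `"trials"` (ids of included trials, spikes or not)
#'   and `"n_skipped"` (trials dropped for a missing event).
#' @export
align_spikes <- function(session, neuron_id, event = "cs_onset",
                         conditions = NULL, cs_types = NULL) {
  col <- vr_event_column(event)
  tr <- session$trials
  tr <- tr[tr$aborted == 0L, ]
  if (!is.null(conditions)) tr <- tr[tr$condition %in% conditions, ]
  if (!is.null(cs_types)) tr <- tr[tr$cs_type %in% cs_types, ]
  missing_ev <- is.na(tr[[col]])
  n_skip <- sum(missing_ev)
  if (n_skip > 0)
    message(n_skip, " trial(s) lack event '", event, "' and were skipped")
  tr <- tr[!missing_ev, ]
  sp <- session$spikes
  sp <- sp[sp$neuron_id == neuron_id & sp$trial_id %in% tr$trial_id, ]
  ev <- tr[[col]][match(sp$trial_id, tr$trial_id)]
  out <- data.frame(trial_id = sp$trial_id, t_rel = sp$spike_time_ms - ev)
  out <- out[order(out$trial_id, out$t_rel), ]
  rownames(out) <- NULL
  attr(out, "trials") <- tr$trial_id
  attr(out, "n_skipped") <- n_skip
  out
}

#' Remove spikes after the ramp stop
#'
#' For CS-aligned analyses of the ramp conditions only spikes emitted while
#' the value was still changing are used. Each trial's valid horizon (its
#' stop time) is kept so averaging can account for the shrinking trial
#' count at late times.
#'
#' @param aligned Output of [align_spikes()] with `event = "cs_onset"`.
#' @param trials Trial table (rows for the aligned trials).
#' @return Same shape as `aligned`, spikes at `t_rel >= stop_time` removed;
#'   attribute `"horizons"` is a named vector (trial_id -> stop time, ms;
#'   `Inf` where no stop event exists).
#' @export
truncate_at_stop <- function(aligned, trials) {
  ids <- attr(aligned, "trials") %||% unique(aligned$trial_id)
  stopt <- trials$stop_time_ms[match(ids, trials$trial_id)]
  stopt[is.na(stopt)] <- Inf
  names(stopt) <- ids
  horiz <- stopt[as.character(aligned$trial_id)]
  out <- aligned[aligned$t_rel < horiz, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trials") <- ids
  attr(out, "n_skipped") <- attr(aligned, "n_skipped")
  attr(out, "horizons") <- stopt
  out
}

#' Spike density function by Gaussian-kernel smoothing
#'
#' Each spike is replaced by a unit-area Gaussian (sigma = 15 ms by
#' default); the per-trial kernel sums are averaged across trials,
#' restricted at every grid point to trials whose valid horizon covers that
#' point (truncation-aware averaging). Rates are in spikes/s.
#'
#' @param aligned Output of [align_spikes()] (optionally truncated).
#' @param grid Time grid, ms relative to the alignment event (default 1 ms
#'   steps over the span of the data).
#' @param kernel_sigma Gaussian SD, ms.
#' @param horizons Optional named vector of per-trial valid horizons (as
#'   attached by [truncate_at_stop()]); defaults to the `"horizons"`
#'   attribute of `aligned`, else no truncation.
#' @return Object of class `"sdf"`: a `data.frame` with `time_ms`, `rate`,
#'   `n_trials`; attributes `kernel_sigma`, `baseline_subtracted`.
#' @export
compute_sdf <- function(aligned, grid = NULL, kernel_sigma = 15,
                        horizons = NULL) {
  ids <- attr(aligned, "trials") %||% unique(aligned$trial_id)
  if (length(ids) == 0)
    stop("no trials to average: zero-trial SDF request")
  if (is.null(horizons)) horizons <- attr(aligned, "horizons")
  if (is.null(horizons)) {
    horizons <- rep(Inf, length(ids)); names(horizons) <- ids
  }
  if (is.null(grid)) {
    lo <- if (nrow(aligned)) floor(min(aligned$t_rel) - 6 * kernel_sigma) else 0
    hi <- if (nrow(aligned)) ceiling(max(aligned$t_rel) + 6 * kernel_sigma) else 1
    grid <- seq(lo, hi, by = 1)
  }
  acc <- numeric(length(grid))
  spk_by_trial <- split(aligned$t_rel, factor(aligned$trial_id, levels = ids))
  # trials covering each grid point
  hmat <- horizons[as.character(ids)]
  n_cov <- colSums(outer(hmat, grid, ">="))
  for (i in seq_along(ids)) {
    st <- spk_by_trial[[i]]
    if (!length(st)) next
    h <- hmat[i]
    for (s in st) {
      # keep the kernel inside this trial's valid horizon so truncated
      # trials do not leak rate past their stop time
      lo <- s - 6 * kernel_sigma; hi <- min(s + 6 * kernel_sigma, h)
      sel <- grid >= lo & grid <= hi
      if (!any(sel)) next
      acc[sel] <- acc[sel] + 1000 * stats::dnorm(grid[sel], s, kernel_sigma)
    }
  }
  rate <- ifelse(n_cov > 0, acc / pmax(n_cov, 1), NA_real_)
  out <- data.frame(time_ms = grid, rate = rate, n_trials = n_cov)
  structure(out, class = c("sdf", "data.frame"),
            kernel_sigma = kernel_sigma, baseline_subtracted = FALSE)
}

#' Subtract a baseline rate from an SDF
#' @param sdf An [compute_sdf()] result.
#' @param baseline Baseline rate, spikes/s.
#' @return The SDF with `rate - baseline` and the flag set.
#' @export
subtract_baseline <- function(sdf, baseline) {
  sdf$rate <- sdf$rate - baseline
  attr(sdf, "baseline_subtracted") <- TRUE
  sdf
}

#' Baseline firing rate (500--0 ms before fixation onset)
#'
#' Mean spike count in the baseline window divided by the window length,
#' averaged over trials.
#'
#' @param session A [session_data()].
#' @param neuron_id Neuron.
#' @param windows An [analysis_windows()].
#' @param conditions Optional condition filter.
#' @param spikes Optional replacement spike table (e.g. a mode-split table
#'   from [split_by_mode()]).
#' @return Rate, spikes/s.
#' @export
baseline_rate <- function(session, neuron_id, windows = analysis_windows(),
                          conditions = NULL, spikes = NULL) {
  if (!is.null(spikes)) session$spikes <- spikes
  al <- align_spikes(session, neuron_id, "fixation_onset",
                     conditions = conditions)
  ids <- attr(al, "trials")
  if (length(ids) == 0) stop("no valid trials for baseline_rate")
  w <- windows$baseline
  counts <- tabulate(match(al$trial_id[al$t_rel >= w[1] & al$t_rel < w[2]],
                           ids), nbins = length(ids))
  mean(counts) / ((w[2] - w[1]) / 1000)
}

#' Binned firing rates over the tonic-fit window
#'
#' Divides the tonic-fit window into `tonic_bin` ms bins and measures the
#' mean rate per bin. Under the default `coverage = "full"` rule a trial
#' contributes to a bin only if its valid horizon covers the whole bin
#' (avoids partial-bin rate bias); `coverage = "partial"` weights each
#' trial by its exposure inside the bin instead (needed for windows that no
#' trial covers completely, such as 600 ms periods under continuous uniform
#' stop times).
#'
#' @param truncated Output of [truncate_at_stop()] (or [align_spikes()] for
#'   untruncated conditions).
#' @param windows An [analysis_windows()].
#' @param breaks Optional explicit bin edges, ms (overrides the tonic
#'   window).
#' @param coverage `"full"` or `"partial"` (see above).
#' @return `data.frame` with `bin_start`, `bin_end`, `center_ms`, `rate`,
#'   `n_trials`; bins with no covering trials have `rate = NA`.
#' @export
bin_rates <- function(truncated, windows = analysis_windows(), breaks = NULL,
                      coverage = c("full", "partial")) {
  coverage <- match.arg(coverage)
  if (is.null(breaks))
    breaks <- seq(windows$tonic_fit[1], windows$tonic_fit[2],
                  by = windows$tonic_bin)
  ids <- attr(truncated, "trials") %||% unique(truncated$trial_id)
  if (!length(ids)) stop("no trials available for bin_rates")
  horiz <- attr(truncated, "horizons")
  if (is.null(horiz)) { horiz <- rep(Inf, length(ids)); names(horiz) <- ids }
  h <- horiz[as.character(ids)]
  nb <- length(breaks) - 1L
  res <- data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1])
  res$center_ms <- (res$bin_start + res$bin_end) / 2
  res$rate <- NA_real_; res$n_trials <- 0L
  last <- nb
  for (b in seq_len(nb)) {
    lo <- res$bin_start[b]; hi <- res$bin_end[b]
    in_bin <- truncated$t_rel >= lo &
      (if (b == last) truncated$t_rel <= hi else truncated$t_rel < hi)
    if (coverage == "full") {
      cov <- h >= hi
      res$n_trials[b] <- sum(cov)
      if (res$n_trials[b] == 0L) next
      cnt <- sum(in_bin & truncated$trial_id %in% ids[cov])
      res$rate[b] <- cnt / res$n_trials[b] / ((hi - lo) / 1000)
    } else {
      expo <- pmax(pmin(h, hi) - lo, 0) / 1000  # seconds of exposure
      res$n_trials[b] <- sum(expo > 0)
      if (sum(expo) <= 0) next
      res$rate[b] <- sum(in_bin) / sum(expo)
    }
  }
  if (all(is.na(res$rate)))
    stop("all bins missing: no trial covers any bin")
  res
}

#' Detect saccade onsets from a gaze trace
#'
#' Positions are despiked with a 3-sample running median and low-passed
#' with a 5-sample moving average, and angular velocity is then taken by
#' central differences over a +-2 sample span; this keeps the velocity
#' noise of a 0.2 deg positional jitter at 240 Hz well below the 40 deg/s
#' threshold while the (zero-phase) smoothing leaves onset timing within
#' about two samples. A saccade onset is the first sample of each run
#' above the velocity threshold, and runs closer than `merge_ms` are
#' merged.
#'
#' @param gaze `data.frame` with `sample_time_ms`, `x_deg`, `y_deg`
#'   (monotone timestamps, near-regular sampling).
#' @param velocity_threshold Threshold, degrees/s (default 40).
#' @param merge_ms Merge window for nearby supra-threshold runs, ms.
#' @return Numeric vector of onset times, ms.
#' @export
detect_saccades <- function(gaze, velocity_threshold = 40, merge_ms = 50) {
  tt <- gaze$sample_time_ms
  if (length(tt) < 3) stop("need at least 3 gaze samples")
  dt <- diff(tt)
  if (any(dt <= 0)) stop("gaze timestamps must be strictly increasing")
  if (max(abs(dt - stats::median(dt))) > 0.1 * stats::median(dt))
    stop("irregular gaze sampling (jitter beyond 10% of the sample period)")
  ma5 <- function(p) as.numeric(stats::filter(p, rep(1 / 5, 5),
                                              sides = 2))
  x <- ma5(stats::runmed(gaze$x_deg, 3))
  y <- ma5(stats::runmed(gaze$y_deg, 3))
  n <- length(tt)
  speed <- numeric(n)
  idx <- 3:(n - 2)
  span <- tt[idx + 2] - tt[idx - 2]
  vx <- (x[idx + 2] - x[idx - 2]) / span * 1000
  vy <- (y[idx + 2] - y[idx - 2]) / span * 1000
  speed[idx] <- sqrt(vx^2 + vy^2)
  speed[is.na(speed)] <- 0
  above <- speed > velocity_threshold
  if (!any(above)) return(numeric(0))
  starts <- which(above & !c(FALSE, above[-n]))
  onsets <- tt[starts]
  if (length(onsets) > 1) {
    keep <- c(TRUE, diff(onsets) > merge_ms)
    # merge a run with its predecessor only if the gap between runs is short
    onsets <- onsets[keep]
  }
  onsets
}
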