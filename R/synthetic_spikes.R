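# Ground-truth neuron models and spike-train simulation.
#
# Firing is the superposition of (a) a smooth component -- baseline rate
# plus a tonic term proportional to the change in cued value since CS
# onset -- generated as an inhomogeneous renewal process by time-rescaling,
# and (b) phasic components -- rectangular rate bumps locked to CS onset
# and to the ramp stop -- generated as an inhomogeneous Poisson process,
# with a configurable fraction of phasic events expanded into short bursts
# (intra-burst ISIs <= 80 ms so they are detectable by the ISI criteria).

#' Ground-truth parameters of one simulated dopamine neuron
#'
#' @param neuron_id Integer id.
#' @param baseline_rate Baseline firing rate lambda0, spikes/s.
#' @param tonic_gain_increase,tonic_gain_decrease Tonic coupling to the
#'   value change (value(t) - value at CS onset), spikes/s per ml, applied
#'   in the value-increase / value-decrease condition respectively. In the
#'   decrease condition the value change is negative, so a positive gain
#'   yields a falling rate.
#' @param cs_phasic_gain Phasic response amplitude at CS onset, spikes/s per
#'   cued value level (value in 0.1 ml units).
#' @param stop_phasic_gain Phasic response amplitude at the ramp stop,
#'   spikes/s per value level; applied with sign `+1` in the value-decrease
#'   condition and `-1` in the value-increase condition (the halt of a
#'   decrease is better, and of an increase worse, than expected).
#' @param cs_kernel,stop_kernel `c(latency_ms, duration_ms)` of the
#'   rectangular phasic kernels. Defaults exactly tile the measurement
#'   windows (100--400 ms after CS, 150--500 ms after stop) so generative
#'   gains equal the regression coefficients they should recover.
#' @param burst_fraction Probability that a phasic spike seeds a burst.
#' @param burst_length_mean Mean number of spikes per burst (>= 2).
#' @param intra_burst_isi Upper bound of intra-burst ISIs, ms (<= 80 so
#'   generated bursts are detectable).
#' @param tonic_mode `"non_burst_dominant"` uses a regular, pacemaker-like
#'   (Erlang-20) renewal process for the smooth component, so tonic and
#'   baseline ISIs stay predominantly above 160 ms and out of the burst
#'   regime; `"mixed"` and `"burst_dominant"` use the Poisson (Erlang-1)
#'   case.
#' @return List of class `"neuron_ground_truth"`.
#' @export
neuron_ground_truth <- function(neuron_id = 1L,
                                baseline_rate = 3.5,
                                tonic_gain_increase = 0,
                                tonic_gain_decrease = 0,
                                cs_phasic_gain = 0,
                                stop_phasic_gain = 0,
                                cs_kernel = c(100, 300),
                                stop_kernel = c(150, 350),
                                burst_fraction = 0.7,
                                burst_length_mean = 3,
                                intra_burst_isi = 60,
                                tonic_mode = c("non_burst_dominant", "mixed",
                                               "burst_dominant")) {
  tonic_mode <- match.arg(tonic_mode)
  stopifnot(baseline_rate >= 0, is.finite(tonic_gain_increase),
            is.finite(tonic_gain_decrease),
            burst_fraction >= 0, burst_fraction <= 1,
            burst_length_mean >= 2, intra_burst_isi > 0,
            intra_burst_isi <= 80)
  structure(list(
    neuron_id = as.integer(neuron_id), baseline_rate = baseline_rate,
    tonic_gain_increase = tonic_gain_increase,
    tonic_gain_decrease = tonic_gain_decrease,
    cs_phasic_gain = cs_phasic_gain, stop_phasic_gain = stop_phasic_gain,
    cs_kernel = cs_kernel, stop_kernel = stop_kernel,
    burst_fraction = burst_fraction, burst_length_mean = burst_length_mean,
    intra_burst_isi = intra_burst_isi, tonic_mode = tonic_mode),
    class = "neuron_ground_truth")
}

# Renewal order of the smooth component per tonic mode. The
# non-burst-dominant mode uses a regular, pacemaker-like process (Erlang-20,
# ISI CV ~ 0.22) so that even at peak tonic rates (~8-9 spikes/s, mean ISI
# ~115 ms) interspike intervals rarely drop to the 80 ms burst-onset
# criterion; Erlang-1 is the inhomogeneous Poisson case.
vr_renewal_shape <- function(tonic_mode) {
  if (tonic_mode == "non_burst_dominant") 20L else 1L
}

# Cued value level (value in 0.1 ml units) of a trial, used to scale the
# phasic kernels.
vr_trial_level <- function(trial, value_unit = 0.1) {
  trial$reward_ml / value_unit
}

#' Analytic firing intensity of the generative model
#'
#' Returns the rate lambda(t) (spikes/s) on a grid of within-trial times,
#' decomposed into a smooth part (baseline + tonic, floored at 0) and a
#' phasic part. Mostly useful for tests that compare empirical rates with
#' the generative intensity.
#'
#' @param neuron A [neuron_ground_truth()].
#' @param trial One trial record (see [sample_trial()]).
#' @param config A [task_config()].
#' @param t_ms Within-trial times, ms.
#' @return `data.frame` with columns `t_ms`, `smooth`, `phasic`, `total`.
#' @export
trial_intensity <- function(neuron, trial, config, t_ms) {
  lam <- vr_intensity_core(neuron, as.list(trial), config, t_ms)
  data.frame(t_ms = t_ms, smooth = lam$smooth, phasic = lam$phasic,
             total = lam$smooth + lam$phasic)
}

# Allocation-lean intensity evaluation; `trial` is a plain list.
vr_intensity_core <- function(neuron, trial, config, t_ms) {
  cs <- trial$cs_onset_ms
  smooth <- rep(neuron$baseline_rate, length(t_ms))
  gain <- if (trial$condition == "value_increase")
    neuron$tonic_gain_increase
  else if (trial$condition == "value_decrease")
    neuron$tonic_gain_decrease
  else 0
  if (gain != 0) {
    in_cs <- t_ms >= cs & t_ms <= cs + config$cs_duration
    te <- pmin(t_ms[in_cs] - cs, trial$stop_time_ms) / 1000
    dv <- if (trial$condition == "value_increase")
      pmin(config$ramp_rate * te,
           config$value_max - config$value_min)
    else
      -pmin(config$ramp_rate * te,
            config$value_max - config$value_min)
    smooth[in_cs] <- smooth[in_cs] + gain * dv
    smooth <- pmax(smooth, 0)
  }
  phasic <- numeric(length(t_ms))
  level <- trial$reward_ml / 0.1
  if (neuron$cs_phasic_gain != 0) {
    k <- neuron$cs_kernel
    cs_level <- if (trial$condition == "value_increase") {
      config$value_min / 0.1
    } else if (trial$condition == "value_decrease") {
      config$value_max / 0.1
    } else level
    amp <- max(neuron$cs_phasic_gain * cs_level, 0)
    on <- t_ms >= cs + k[1] & t_ms < cs + k[1] + k[2]
    phasic[on] <- phasic[on] + amp
  }
  if (neuron$stop_phasic_gain != 0 && length(trial$stop_onset_ms) &&
        !is.na(trial$stop_onset_ms)) {
    k <- neuron$stop_kernel
    sgn <- if (trial$condition == "value_decrease") 1 else -1
    amp <- max(sgn * neuron$stop_phasic_gain * level, 0)
    on <- t_ms >= trial$stop_onset_ms + k[1] &
      t_ms < trial$stop_onset_ms + k[1] + k[2]
    phasic[on] <- phasic[on] + amp
  }
  list(smooth = smooth, phasic = phasic)
}

# Draw an equilibrium-start Erlang-k renewal process in rescaled (unit-rate)
# time up to total integrated intensity `target`. Returns event positions in
# rescaled time. Equilibrium start: the forward recurrence time of an
# Erlang(k) interval is an equal-weight mixture of Erlang(1..k).
vr_renewal_rescaled <- function(target, k) {
  if (target <= 0) return(numeric(0))
  mean_isi <- 1  # unit-rate process: Erlang(k, k)
  n_guess <- max(10L, ceiling(target / mean_isi * 1.5 + 4 * sqrt(target)))
  first <- stats::rgamma(1, shape = sample.int(k, 1L), rate = k)
  isis <- stats::rgamma(n_guess, shape = k, rate = k)
  times <- cumsum(c(first, isis))
  while (times[length(times)] < target) {
    isis <- stats::rgamma(n_guess, shape = k, rate = k)
    times <- c(times, times[length(times)] + cumsum(isis))
  }
  times[times <= target]
}

#' Simulate one trial's spike train for one neuron
#'
#' Smooth (baseline + tonic) spikes come from an inhomogeneous renewal
#' process obtained by time-rescaling Erlang-k interspike intervals through
#' the integrated intensity (k = 1 is the inhomogeneous Poisson special
#' case); phasic spikes come from an inhomogeneous Poisson process on the
#' kernel intensity, and a `burst_fraction` of them is expanded into bursts
#' of >= 2 spikes with intra-burst ISIs bounded by `intra_burst_isi`. A 3 ms
#' absolute refractory period is enforced on the merged train. Every spike
#' carries a provenance tag (`baseline`, `tonic`, `phasic`, `burst`) for
#' white-box testing.
#'
#' @inheritParams trial_intensity
#' @param dt_ms Grid step used to integrate the intensity, ms.
#' @return Numeric vector of spike times (ms, within-trial), sorted, with a
#'   character attribute `"source"` of equal length.
#' @export
simulate_trial_spikes <- function(neuron, trial, config, dt_ms = 1) {
  trial <- as.list(trial)
  if (isTRUE(trial$aborted == 1L))
    stop("cannot simulate spikes for an aborted trial")
  t_end <- trial$reward_onset_ms + 500
  grid <- seq.int(0, t_end, by = dt_ms)
  lam <- vr_intensity_core(neuron, trial, config, grid)

  # --- smooth component: time-rescaled Erlang-k renewal -------------------
  k <- vr_renewal_shape(neuron$tonic_mode)
  cum <- cumsum(lam$smooth) * dt_ms / 1000  # integrated intensity (expected
  cum <- cum - cum[1]                       # spikes) along the grid
  total <- cum[length(cum)]
  sm_times <- numeric(0)
  if (total > 0) {
    resc <- vr_renewal_rescaled(total, k)
    if (length(resc))
      sm_times <- stats::approx(cum, grid, xout = resc, ties = "ordered")$y
  }
  sm_src <- rep("baseline", length(sm_times))
  if (length(sm_times)) {
    # attribute each smooth spike to baseline vs tonic by intensity share
    idx <- pmin(pmax(round(sm_times / dt_ms) + 1, 1), length(grid))
    p_tonic <- 1 - pmin(neuron$baseline_rate, lam$smooth[idx]) /
      pmax(lam$smooth[idx], 1e-12)
    sm_src[stats::runif(length(sm_times)) < p_tonic] <- "tonic"
  }

  # --- phasic component: inhomogeneous Poisson + burst expansion ----------
  ph_times <- numeric(0); ph_src <- character(0)
  cum_p <- cumsum(lam$phasic) * dt_ms / 1000
  tot_p <- cum_p[length(cum_p)]
  if (tot_p > 0) {
    n <- stats::rpois(1, tot_p)
    if (n > 0) {
      u <- sort(stats::runif(n, 0, tot_p))
      seeds <- stats::approx(cum_p, grid, xout = u, ties = "ordered")$y
      for (s in seeds) {
        ph_times <- c(ph_times, s); ph_src <- c(ph_src, "phasic")
        if (stats::runif(1) < neuron$burst_fraction) {
          extra <- 1L + stats::rpois(1, neuron$burst_length_mean - 2)
          if (extra > 0) {
            isis <- stats::runif(extra, 15, neuron$intra_burst_isi)
            bt <- s + cumsum(isis)
            bt <- bt[bt <= t_end]
            ph_times <- c(ph_times, bt)
            ph_src <- c(ph_src, rep("burst", length(bt)))
          }
        }
      }
    }
  }

  times <- c(sm_times, ph_times)
  src <- c(sm_src, ph_src)
  o <- order(times)
  times <- times[o]; src <- src[o]
  # absolute refractory period: drop the later spike of any < 3 ms pair
  if (length(times) > 1) {
    keep <- rep(TRUE, length(times))
    last <- times[1]
    for (i in 2:length(times)) {
      if (times[i] - last < 3) keep[i] <- FALSE else last <- times[i]
    }
    times <- times[keep]; src <- src[keep]
  }
  attr(times, "source") <- src
  times
}
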