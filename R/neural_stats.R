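# Estimators and tests: tonic slope regression, cue/stop value regressions,
# slope comparison, gaze-rate correlations, the neuron-resampling bootstrap,
# the logistic choice fit, and neuron classification.

vr_slope_fit <- function(x, y) {
  # OLS of y on x with a two-sided t-test on the slope; degenerate
  # zero-residual fits get p = 1 (flat) or p = 0 (perfect non-flat line).
  n <- length(x)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-12 * max(1, sum(y^2))) {
    se <- 0
    p <- if (abs(slope) < 1e-12) 1 else 0
  } else {
    se <- summary(fit)$coefficients[2, 2]
    p <- summary(fit)$coefficients[2, 4]
  }
  list(slope = slope, intercept = intercept, se = se, p_value = p, n = n)
}

#' Tonic slope: regression of binned firing rate on time
#'
#' Ordinary least squares of the across-trial mean rate in each 200 ms bin
#' on the time at the bin center (in seconds), with a two-sided t-test on
#' the slope. Missing bins are dropped; fewer than 3 usable bins makes the
#' fit unusable.
#'
#' @param bins Output of [bin_rates()].
#' @param condition Optional label stored in the result.
#' @return List of class `"time_slope"`: `slope` (spikes/s per s),
#'   `intercept`, `slope_se`, `p_value`, `n_bins`, `condition`, `usable`.
#' @export
fit_time_slope <- function(bins, condition = NA_character_) {
  ok <- !is.na(bins$rate)
  if (sum(ok) < 3) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          slope_se = NA_real_, p_value = NA_real_,
                          n_bins = sum(ok), condition = condition,
                          usable = FALSE), class = "time_slope"))
  }
  f <- vr_slope_fit(bins$center_ms[ok] / 1000, bins$rate[ok])
  structure(list(slope = f$slope, intercept = f$intercept, slope_se = f$se,
                 p_value = f$p_value, n_bins = sum(ok),
                 condition = condition, usable = TRUE),
            class = "time_slope")
}

vr_window_rates <- function(aligned, window, trial_ids) {
  counts <- tabulate(match(
    aligned$trial_id[aligned$t_rel >= window[1] & aligned$t_rel < window[2]],
    trial_ids), nbins = length(trial_ids))
  counts / ((window[2] - window[1]) / 1000)
}

#' Cue-response value regression (value-fixed condition)
#'
#' Regresses each trial's firing rate in the 100--400 ms window after CS
#' onset on the cued reward value. Uncertain-CS trials are excluded (their
#' cue does not reveal the value). Default value coding is levels in
#' 0.1 ml units (1, 2, 3); ml coding rescales the coefficient only.
#'
#' @param session A [session_data()].
#' @param neuron_id Neuron.
#' @param windows An [analysis_windows()].
#' @param value_coding `"level_0p1ml"` or `"ml"`.
#' @param spikes Optional replacement spike table (mode-split analyses).
#' @return List of class `"value_regression"`: `coefficient`, `se`,
#'   `p_value`, `value_coding`, `alignment = "cue"`, `n_trials`.
#' @export
fit_value_regression_cue <- function(session, neuron_id,
                                     windows = analysis_windows(),
                                     value_coding = c("level_0p1ml", "ml"),
                                     spikes = NULL) {
  value_coding <- match.arg(value_coding)
  if (!is.null(spikes)) session$spikes <- spikes
  al <- align_spikes(session, neuron_id, "cs_onset",
                     conditions = "value_fixed",
                     cs_types = c("fixed_small", "fixed_medium",
                                  "fixed_large"))
  ids <- attr(al, "trials")
  tr <- session$trials[match(ids, session$trials$trial_id), ]
  present <- unique(tr$cs_type)
  absent <- setdiff(c("fixed_small", "fixed_medium", "fixed_large"), present)
  if (length(absent))
    stop("value level(s) missing from the value-fixed data: ",
         paste(absent, collapse = ", "))
  rate <- vr_window_rates(al, windows$cue_response, ids)
  v <- if (value_coding == "ml") tr$reward_ml else tr$reward_ml / 0.1
  f <- vr_slope_fit(v, rate)
  structure(list(coefficient = f$slope, se = f$se, p_value = f$p_value,
                 value_coding = value_coding, alignment = "cue",
                 n_trials = length(ids)), class = "value_regression")
}

#' Stop-response value regression (ramp conditions)
#'
#' Trials of one ramp condition are grouped into small/medium/large reward
#' groups; each group's mean firing rate in the 150--500 ms window after
#' the stop is regressed on the group's mean reward value (0.1 ml units by
#' default). The fit has three points and one residual degree of freedom.
#'
#' @inheritParams fit_value_regression_cue
#' @param condition `"value_increase"` or `"value_decrease"`.
#' @return List of class `"value_regression"` with `alignment = "stop"`,
#'   `n_groups = 3`, plus the per-group table.
#' @export
fit_value_regression_stop <- function(session, neuron_id, condition,
                                      windows = analysis_windows(),
                                      value_coding = c("level_0p1ml", "ml"),
                                      spikes = NULL) {
  value_coding <- match.arg(value_coding)
  if (!condition %in% c("value_increase", "value_decrease"))
    stop("stop-aligned regression needs one ramp condition at a time")
  if (!is.null(spikes)) session$spikes <- spikes
  al <- align_spikes(session, neuron_id, "stop_onset",
                     conditions = condition)
  ids <- attr(al, "trials")
  tr <- session$trials[match(ids, session$trials$trial_id), ]
  vg <- windows$value_groups
  grp <- rep(NA_integer_, nrow(tr))
  for (g in seq_len(nrow(vg))) {
    upper_ok <- if (g == nrow(vg)) tr$reward_ml <= vg[g, 2]
    else tr$reward_ml < vg[g, 2]
    grp[tr$reward_ml >= vg[g, 1] & upper_ok] <- g
  }
  occ <- tabulate(grp, nbins = nrow(vg))
  if (any(occ == 0))
    stop("empty value group(s): occupancy ",
         paste(sprintf("%s=%d", rownames(vg), occ), collapse = ", "))
  rate <- vr_window_rates(al, windows$stop_response, ids)
  gr_rate <- tapply(rate, grp, mean)
  gr_val <- tapply(tr$reward_ml, grp, mean)
  v <- if (value_coding == "ml") gr_val else gr_val / 0.1
  f <- vr_slope_fit(as.numeric(v), as.numeric(gr_rate))
  structure(list(coefficient = f$slope, se = f$se, p_value = f$p_value,
                 value_coding = value_coding, alignment = "stop",
                 n_groups = nrow(vg), condition = condition,
                 groups = data.frame(group = rownames(vg), n = occ,
                                     mean_value_ml = as.numeric(gr_val),
                                     mean_rate = as.numeric(gr_rate))),
            class = "value_regression")
}

#' Compare two regression slopes
#'
#' Two-sided z-test on the difference of two independent slopes:
#' `z = (b_a - b_b) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param fit_a,fit_b [fit_time_slope()] results (or any list with `slope`
#'   and `slope_se`).
#' @return List with `z` and `p_value`.
#' @export
compare_two_slopes <- function(fit_a, fit_b) {
  se <- sqrt(fit_a$slope_se^2 + fit_b$slope_se^2)
  d <- fit_a$slope - fit_b$slope
  if (se == 0) {
    if (d == 0) return(list(z = 0, p_value = 1))
    stop("zero combined standard error with unequal slopes")
  }
  z <- d / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Per-bin correlation between firing rate and vertical gaze position
#'
#' For each 200 ms bin of the tonic-fit window (trials with whole-bin stop
#' coverage only), computes the Pearson correlation across trials between
#' the bin firing rate and the mean vertical gaze position in the bin.
#'
#' @param session A [session_data()] with a gaze table.
#' @param neuron_id Neuron.
#' @param condition Ramp condition to analyse.
#' @param windows An [analysis_windows()].
#' @return `data.frame` with `center_ms`, `r`, `p_value`, `n_trials`;
#'   degenerate bins (fewer than 3 trials or zero variance) have `NA`.
#' @export
gaze_rate_correlation <- function(session, neuron_id, condition,
                                  windows = analysis_windows()) {
  if (is.null(session$gaze)) stop("session has no gaze table")
  al <- align_spikes(session, neuron_id, "cs_onset", conditions = condition)
  tru <- truncate_at_stop(al, session$trials)
  ids <- attr(tru, "trials")
  horiz <- attr(tru, "horizons")[as.character(ids)]
  tr <- session$trials[match(ids, session$trials$trial_id), ]
  breaks <- seq(windows$tonic_fit[1], windows$tonic_fit[2],
                by = windows$tonic_bin)
  out <- data.frame(center_ms = (breaks[-length(breaks)] + breaks[-1]) / 2,
                    r = NA_real_, p_value = NA_real_, n_trials = 0L)
  gz <- session$gaze[session$gaze$trial_id %in% ids, ]
  gz$t_rel <- gz$sample_time_ms -
    tr$cs_onset_ms[match(gz$trial_id, tr$trial_id)]
  for (b in seq_len(nrow(out))) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    cov_ids <- ids[horiz >= hi]
    if (length(cov_ids) < 3) next
    cnt <- tabulate(match(
      tru$trial_id[tru$t_rel >= lo & tru$t_rel < hi], cov_ids),
      nbins = length(cov_ids))
    rate <- cnt / ((hi - lo) / 1000)
    gsel <- gz[gz$trial_id %in% cov_ids & gz$t_rel >= lo & gz$t_rel < hi, ]
    ypos <- tapply(gsel$y_deg, factor(gsel$trial_id, levels = cov_ids), mean)
    out$n_trials[b] <- length(cov_ids)
    if (stats::sd(rate) == 0 || any(is.na(ypos)) ||
          stats::sd(ypos, na.rm = TRUE) == 0) next
    ct <- stats::cor.test(rate, as.numeric(ypos))
    out$r[b] <- unname(ct$estimate); out$p_value[b] <- ct$p.value
  }
  out
}

#' Bootstrap configuration for the firing-mode comparison
#' @param n_repetitions Number of resamples (1000).
#' @param significance_count Count of one sign needed for significance
#'   (more than 975 of 1000, i.e. two-sided p < 0.05).
#' @return List of class `"bootstrap_config"`.
#' @export
bootstrap_config <- function(n_repetitions = 1000,
                             significance_count = 975) {
  structure(list(n_repetitions = n_repetitions,
                 significance_count = significance_count),
            class = "bootstrap_config")
}

#' Neuron-resampling bootstrap comparing burst and non-burst firing
#'
#' For each period, neurons are resampled with replacement (same n) and the
#' population means of the baseline-subtracted rates of the two modes are
#' compared; the sign of each comparison is counted over the repetitions.
#' The difference is significant when one sign occurs in more than
#' `significance_count` repetitions; exact ties count toward neither sign.
#'
#' @param deltas `data.frame` with one row per neuron x period:
#'   `neuron_id`, `period`, `delta_non_burst`, `delta_burst` (spikes/s,
#'   baseline-subtracted). Neurons with missing values are excluded with a
#'   message.
#' @param config A [bootstrap_config()].
#' @param seed Optional integer seed.
#' @return `data.frame` per period: counts of each sign, ties, the
#'   significance flag and direction.
#' @export
bootstrap_mode_comparison <- function(deltas, config = bootstrap_config(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bad <- unique(deltas$neuron_id[!stats::complete.cases(
    deltas[, c("delta_non_burst", "delta_burst")])])
  if (length(bad)) {
    message("excluding ", length(bad), " neuron(s) with missing mode data")
    deltas <- deltas[!deltas$neuron_id %in% bad, ]
  }
  if (!nrow(deltas)) stop("no neurons available for the bootstrap")
  periods <- unique(deltas$period)
  out <- list()
  for (p in periods) {
    d <- deltas[deltas$period == p, ]
    n <- nrow(d)
    if (n == 0) stop("no neurons available for period ", p)
    idx <- matrix(sample.int(n, n * config$n_repetitions, replace = TRUE),
                  nrow = config$n_repetitions)
    nb <- matrix(d$delta_non_burst[idx], nrow = config$n_repetitions)
    bu <- matrix(d$delta_burst[idx], nrow = config$n_repetitions)
    diffm <- rowMeans(nb) - rowMeans(bu)
    n_nb <- sum(diffm > 0); n_b <- sum(diffm < 0)
    sig <- max(n_nb, n_b) > config$significance_count
    out[[length(out) + 1L]] <- data.frame(
      period = p, n_neurons = n, count_non_burst_larger = n_nb,
      count_burst_larger = n_b,
      count_tie = config$n_repetitions - n_nb - n_b,
      significant = sig,
      direction = if (!sig) NA_character_ else
        if (n_nb >= n_b) "non_burst" else "burst")
  }
  as.data.frame(data.table::rbindlist(out))
}

#' Per-neuron, per-period baseline-subtracted rates by firing mode
#'
#' Computes, for each requested neuron, the burst and non-burst firing
#' rates in the initial/middle/late periods of the CS-aligned, stop-
#' truncated ramp-condition activity (exposure-weighted partial coverage,
#' since under continuous uniform stop times no trial covers a full 600 ms
#' period), minus the same mode's baseline rate (mode-specific baseline).
#'
#' @param session A [session_data()].
#' @param neuron_ids Neurons to include.
#' @param condition Ramp condition (default `"value_increase"`).
#' @param windows An [analysis_windows()].
#' @param criteria A [burst_criteria()].
#' @param baseline `"per_mode"` (default) or `"overall"`.
#' @return `data.frame` suitable for [bootstrap_mode_comparison()].
#' @export
mode_period_deltas <- function(session, neuron_ids,
                               condition = "value_increase",
                               windows = analysis_windows(),
                               criteria = burst_criteria(),
                               baseline = c("per_mode", "overall")) {
  baseline <- match.arg(baseline)
  out <- list()
  pm <- windows$periods
  for (nid in neuron_ids) {
    modes <- split_by_mode(session, nid, criteria)
    rates <- list()
    for (m in c("non_burst", "burst")) {
      base <- baseline_rate(session, nid, windows,
                            spikes = if (baseline == "per_mode")
                              modes[[m]] else NULL)
      s2 <- session; s2$spikes <- modes[[m]]
      al <- align_spikes(s2, nid, "cs_onset", conditions = condition)
      tru <- truncate_at_stop(al, session$trials)
      pr <- bin_rates(tru, windows,
                      breaks = c(pm[, 1], pm[nrow(pm), 2]),
                      coverage = "partial")
      rates[[m]] <- pr$rate - base
    }
    out[[length(out) + 1L]] <- data.frame(
      neuron_id = nid, period = rownames(pm),
      delta_non_burst = rates$non_burst, delta_burst = rates$burst)
  }
  as.data.frame(data.table::rbindlist(out))
}

#' Logistic fit of choice on the value difference
#'
#' Maximum-likelihood fit of `P(choice = right)` on `v_right - v_left`
#' under `P = 1 / (1 + exp(-(beta0 + beta1 * dv)))`. Complete separation
#' raises an error unless `penalized = TRUE`, which adds a small L2 penalty.
#'
#' @param choices `data.frame` with `v_right`, `v_left`, `choice_right`.
#' @param penalized Use an L2-penalized fit (lambda = 1e-3) as fallback.
#' @return List of class `"choice_model"`: `beta0`, `beta1`, `se0`, `se1`,
#'   `n_trials`.
#' @export
fit_choice_logistic <- function(choices, penalized = FALSE) {
  dv <- choices$v_right - choices$v_left
  y <- choices$choice_right
  if (length(unique(y)) < 2)
    stop("need both outcomes present for a logistic fit")
  # with a single predictor, complete separation is exactly a non-overlap
  # of the dv ranges of the two outcomes
  separated <- max(dv[y == 0]) < min(dv[y == 1]) ||
    max(dv[y == 1]) < min(dv[y == 0])
  if (separated && !penalized)
    stop("complete separation detected; refit with penalized = TRUE")
  if (penalized) {
    nll <- function(b) {
      eta <- b[1] + b[2] * dv
      sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
        1e-3 * sum(b^2)
    }
    op <- stats::optim(c(0, 0), nll, hessian = TRUE, method = "BFGS")
    se <- sqrt(diag(solve(op$hessian)))
    return(structure(list(beta0 = op$par[1], beta1 = op$par[2],
                          se0 = se[1], se1 = se[2],
                          n_trials = length(y), penalized = TRUE),
                     class = "choice_model"))
  }
  fit <- withCallingHandlers(
    stats::glm(y ~ dv, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("complete separation detected; refit with penalized = TRUE",
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  structure(list(beta0 = co[1, 1], beta1 = co[2, 1],
                 se0 = co[1, 2], se1 = co[2, 2],
                 n_trials = length(y), penalized = FALSE),
            class = "choice_model")
}

#' Fit and classify one neuron
#'
#' Runs every per-neuron estimator -- baseline rates per condition, tonic
#' slopes in the two ramp conditions and in the uncertain-CS trials of the
#' value-fixed condition, the cue- and stop-aligned value regressions --
#' and derives the classification flags: `tonic_increaser` (value-increase
#' slope > 0, p < 0.05), `tonic_decreaser` (value-decrease slope < 0,
#' p < 0.05), `cue_value_coder` and the per-condition `stop_value_coder`
#' flags (coefficient significant at p < 0.05). Failed component fits
#' yield `NA` flags.
#'
#' @param session A [session_data()].
#' @param neuron_id Neuron.
#' @param windows An [analysis_windows()].
#' @param alpha Significance level for the flags.
#' @return One-row `data.frame` (a NeuronSummary record).
#' @export
classify_neuron <- function(session, neuron_id,
                            windows = analysis_windows(), alpha = 0.05) {
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  base_by <- vapply(VR_CONDITIONS, function(cond)
    tryCatch(baseline_rate(session, neuron_id, windows, conditions = cond),
             error = function(e) NA_real_), numeric(1))
  slope_for <- function(cond, cs_types = NULL) {
    safe({
      al <- align_spikes(session, neuron_id, "cs_onset", conditions = cond,
                         cs_types = cs_types)
      tru <- truncate_at_stop(al, session$trials)
      fit_time_slope(bin_rates(tru, windows), condition = cond)
    })
  }
  s_inc <- slope_for("value_increase")
  s_dec <- slope_for("value_decrease")
  s_unc <- slope_for("value_fixed", cs_types = "uncertain")
  cue <- safe(fit_value_regression_cue(session, neuron_id, windows))
  st_inc <- safe(fit_value_regression_stop(session, neuron_id,
                                           "value_increase", windows))
  st_dec <- safe(fit_value_regression_stop(session, neuron_id,
                                           "value_decrease", windows))
  gv <- function(x, f) if (is.null(x) || isFALSE(x$usable %||% TRUE))
    NA_real_ else x[[f]]
  flag <- function(est, p, dir = 0) {
    if (is.na(est) || is.na(p)) return(NA)
    sig <- p < alpha
    if (dir > 0) sig && est > 0 else if (dir < 0) sig && est < 0 else sig
  }
  data.frame(
    neuron_id = neuron_id,
    baseline_fixed = base_by[["value_fixed"]],
    baseline_increase = base_by[["value_increase"]],
    baseline_decrease = base_by[["value_decrease"]],
    slope_increase = gv(s_inc, "slope"),
    slope_increase_se = gv(s_inc, "slope_se"),
    slope_increase_p = gv(s_inc, "p_value"),
    slope_decrease = gv(s_dec, "slope"),
    slope_decrease_se = gv(s_dec, "slope_se"),
    slope_decrease_p = gv(s_dec, "p_value"),
    slope_uncertain = gv(s_unc, "slope"),
    slope_uncertain_p = gv(s_unc, "p_value"),
    cue_coef = gv(cue, "coefficient"),
    cue_coef_se = gv(cue, "se"),
    cue_coef_p = gv(cue, "p_value"),
    stop_coef_increase = gv(st_inc, "coefficient"),
    stop_coef_increase_p = gv(st_inc, "p_value"),
    stop_coef_decrease = gv(st_dec, "coefficient"),
    stop_coef_decrease_p = gv(st_dec, "p_value"),
    tonic_increaser = flag(gv(s_inc, "slope"), gv(s_inc, "p_value"), 1),
    tonic_decreaser = flag(gv(s_dec, "slope"), gv(s_dec, "p_value"), -1),
    cue_value_coder = flag(gv(cue, "coefficient"), gv(cue, "p_value")),
    stop_value_coder_increase = flag(gv(st_inc, "coefficient"),
                                     gv(st_inc, "p_value")),
    stop_value_coder_decrease = flag(gv(st_dec, "coefficient"),
                                     gv(st_dec, "p_value")))
}

#' Classify every neuron of a session
#' @inheritParams classify_neuron
#' @return `data.frame`, one row per neuron (NeuronSummary table).
#' @export
summarize_population <- function(session, windows = analysis_windows(),
                                 alpha = 0.05) {
  ids <- sort(unique(session$spikes$neuron_id))
  as.data.frame(data.table::rbindlist(
    lapply(ids, function(i) classify_neuron(session, i, windows, alpha))))
}

#' Cross-neuron correlations between tonic and phasic coding
#'
#' Pearson correlations between the per-neuron tonic slopes and the phasic
#' value-regression coefficients (the tonic--phasic relationship panels).
#'
#' @param summary A [summarize_population()] table.
#' @return `data.frame` with variable pair, `r`, `p_value`, `n`.
#' @export
population_correlations <- function(summary) {
  pairs <- list(
    c("slope_increase", "cue_coef"),
    c("slope_decrease", "cue_coef"),
    c("slope_increase", "stop_coef_increase"),
    c("slope_decrease", "stop_coef_decrease"))
  out <- lapply(pairs, function(p) {
    x <- summary[[p[1]]]; y <- summary[[p[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3)
      return(data.frame(var_x = p[1], var_y = p[2], r = NA_real_,
                        p_value = NA_real_, n = sum(ok)))
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(var_x = p[1], var_y = p[2], r = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok))
  })
  as.data.frame(data.table::rbindlist(out))
}
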