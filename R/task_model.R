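# Executable model of the Pavlovian value-ramp task: value trajectories,
# stop-time sampling, CS types, reward schedules and block structure.

VR_CONDITIONS <- c("value_fixed", "value_increase", "value_decrease")
VR_CS_TYPES <- c("ramp", "fixed_small", "fixed_medium", "fixed_large",
                 "uncertain")

#' Task configuration for the Pavlovian value-ramp task
#'
#' Collects every task constant in one validated place. Defaults encode the
#' standard design: the cued reward value ramps between 0.1 and 0.3 ml at
#' 0.082 ml/s, the ramp stops at a time drawn uniformly on 0--2450 ms after
#' CS onset, the CS stays on for 2850 ms, and each condition is run as a
#' block of 50 trials. Times are milliseconds within a trial; trial start
#' (t = 0) is `pre_fixation_ms` before the fixation-point onset so that the
#' 500 ms pre-fixation baseline window has non-negative times.
#'
#' @param ramp_rate Reward change rate during the ramp, ml/s.
#' @param value_min,value_max Reward bounds, ml.
#' @param fixed_levels Reward amounts cued by the three fixed CSs, ml.
#' @param stop_window Interval (ms after CS onset) on which the ramp stop
#'   time is uniform.
#' @param cs_duration CS presentation time, ms; reward is delivered at CS
#'   offset.
#' @param fixation_duration Required fixation before CS onset, ms.
#' @param pre_fixation_ms Recording lead time before fixation onset, ms
#'   (must cover the 500 ms baseline window).
#' @param block_size Trials per condition block.
#' @param cs_probability Probability of each of the four CS types in the
#'   value-fixed condition.
#' @param uncertain_reward_interval Reward interval (ml) for the uncertain
#'   CS.
#' @param block_order Condition labels in block presentation order.
#' @param quantize_stop_ms Optional quantum (ms) for stop-time draws; `NULL`
#'   keeps the continuous uniform.
#' @param abort_rate Probability that a simulated trial is aborted by a
#'   fixation break (excluded from analyses); default 0.
#' @return A validated list of class `"task_config"`.
#' @examples
#' cfg <- task_config()
#' value_at_time(cfg, "value_increase", stop_time = 2450, t = 2450)
#' @export
task_config <- function(ramp_rate = 0.082,
                        value_min = 0.1,
                        value_max = 0.3,
                        fixed_levels = c(0.1, 0.2, 0.3),
                        stop_window = c(0, 2450),
                        cs_duration = 2850,
                        fixation_duration = 400,
                        pre_fixation_ms = 1000,
                        block_size = 50,
                        cs_probability = rep(0.25, 4),
                        uncertain_reward_interval = c(0.1, 0.3),
                        block_order = c("value_fixed", "value_increase",
                                        "value_decrease"),
                        quantize_stop_ms = NULL,
                        abort_rate = 0) {
  cfg <- list(
    ramp_rate = ramp_rate, value_min = value_min, value_max = value_max,
    fixed_levels = sort(fixed_levels), stop_window = stop_window,
    cs_duration = cs_duration, fixation_duration = fixation_duration,
    pre_fixation_ms = pre_fixation_ms, block_size = block_size,
    cs_probability = cs_probability,
    uncertain_reward_interval = uncertain_reward_interval,
    block_order = block_order, quantize_stop_ms = quantize_stop_ms,
    abort_rate = abort_rate)
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(cfg$value_min < cfg$value_max,
            cfg$ramp_rate > 0,
            length(cfg$stop_window) == 2,
            cfg$stop_window[1] <= cfg$stop_window[2])
  if (cfg$cs_duration <= 0 || cfg$fixation_duration <= 0 ||
      cfg$pre_fixation_ms < 500)
    stop("durations must be positive and pre_fixation_ms >= 500 ms")
  if (cfg$stop_window[1] < 0 || cfg$stop_window[2] > cfg$cs_duration)
    stop("stop_window must lie within [0, cs_duration]")
  if (abs(sum(cfg$cs_probability) - 1) > 1e-8)
    stop("cs_probability must sum to 1")
  if (!all(cfg$block_order %in% VR_CONDITIONS))
    stop("unknown condition label in block_order")
  # full-length ramp must span the value range (to within 1%)
  span <- cfg$ramp_rate * cfg$stop_window[2] / 1000
  if (abs(span - (cfg$value_max - cfg$value_min)) >
      0.01 * (cfg$value_max - cfg$value_min))
    stop("ramp_rate x stop window does not span [value_min, value_max]")
  if (cfg$abort_rate < 0 || cfg$abort_rate >= 1)
    stop("abort_rate must be in [0, 1)")
  invisible(cfg)
}

vr_check_condition <- function(condition) {
  if (length(condition) != 1L || !condition %in% VR_CONDITIONS)
    stop("unknown condition '", paste(condition, collapse = ","),
         "'; expected one of ", paste(VR_CONDITIONS, collapse = ", "))
  condition
}

#' Cued reward value at a time during the CS period
#'
#' Piecewise-linear value trajectory: in the value-increase condition the
#' value starts at `value_min` and rises at `ramp_rate` until `stop_time`,
#' then stays constant; the value-decrease condition mirrors this from
#' `value_max` downward. Values are clamped to `[value_min, value_max]`.
#' For the value-fixed condition the trajectory is flat at `fixed_value`.
#'
#' @param config A [task_config()].
#' @param condition One of `"value_increase"`, `"value_decrease"`,
#'   `"value_fixed"`.
#' @param stop_time Ramp stop time, ms after CS onset (ignored for
#'   value-fixed).
#' @param t Time(s) after CS onset, ms; vectorised.
#' @param fixed_value Cued value for the value-fixed condition, ml.
#' @return Reward value(s), ml.
#' @export
value_at_time <- function(config, condition, stop_time = NULL, t,
                          fixed_value = NULL) {
  vr_check_condition(condition)
  if (any(t < 0)) stop("t must be non-negative (ms after CS onset)")
  if (any(t > config$cs_duration))
    stop("t beyond the CS period (cs_duration = ", config$cs_duration, " ms)")
  if (condition == "value_fixed") {
    if (is.null(fixed_value))
      stop("value_fixed trajectories need `fixed_value` (no ramp)")
    return(rep(fixed_value, length(t)))
  }
  if (is.null(stop_time) || is.na(stop_time))
    stop("ramp conditions require a stop_time")
  if (stop_time < config$stop_window[1] || stop_time > config$stop_window[2])
    stop("stop_time outside the configured stop window")
  te <- pmin(t, stop_time) / 1000  # s of elapsed ramp
  v <- if (condition == "value_increase")
    config$value_min + config$ramp_rate * te
  else
    config$value_max - config$ramp_rate * te
  pmin(pmax(v, config$value_min), config$value_max)
}

#' Sample one trial of the Pavlovian task
#'
#' Ramp conditions draw a stop time uniform on the stop window and set the
#' reward to the value reached at that time; the value-fixed condition draws
#' one of four CS types with equal probability (three fixed amounts plus an
#' uncertain CS whose reward is uniform on `uncertain_reward_interval`).
#' Event times are laid out as trial start (0) -> fixation onset
#' (`pre_fixation_ms`) -> CS onset (+`fixation_duration`) -> reward onset
#' (+`cs_duration`).
#'
#' @inheritParams value_at_time
#' @param trial_id,block_index Identifiers stamped into the record.
#' @return One-row `data.frame` (a `TrialSpec` record).
#' @export
sample_trial <- function(config, condition, trial_id = 1L, block_index = 1L) {
  vr_check_condition(condition)
  fo <- config$pre_fixation_ms
  cs <- fo + config$fixation_duration
  ro <- cs + config$cs_duration
  stop_time <- NA_real_
  if (condition == "value_fixed") {
    cs_type <- sample(VR_CS_TYPES[-1], 1L, prob = config$cs_probability)
    reward <- switch(cs_type,
      fixed_small  = config$fixed_levels[1],
      fixed_medium = config$fixed_levels[2],
      fixed_large  = config$fixed_levels[3],
      uncertain    = stats::runif(1, config$uncertain_reward_interval[1],
                                  config$uncertain_reward_interval[2]))
  } else {
    cs_type <- "ramp"
    stop_time <- stats::runif(1, config$stop_window[1], config$stop_window[2])
    if (!is.null(config$quantize_stop_ms))
      stop_time <- round(stop_time / config$quantize_stop_ms) *
        config$quantize_stop_ms
    reward <- value_at_time(config, condition, stop_time, stop_time)
  }
  aborted <- as.integer(config$abort_rate > 0 &&
                          stats::runif(1) < config$abort_rate)
  data.frame(
    trial_id = as.integer(trial_id), block_index = as.integer(block_index),
    condition = condition, cs_type = cs_type,
    stop_time_ms = stop_time, reward_ml = reward,
    fixation_onset_ms = fo, cs_onset_ms = cs,
    stop_onset_ms = if (is.na(stop_time)) NA_real_ else cs + stop_time,
    reward_onset_ms = ro, aborted = aborted,
    stringsAsFactors = FALSE)
}

#' Sample a block of trials for one condition
#'
#' @inheritParams sample_trial
#' @param n Number of trials; defaults to the configured block size.
#' @param first_trial_id Id of the first trial in the block.
#' @return `data.frame` of trial records.
#' @export
sample_block <- function(config, condition, n = config$block_size,
                         block_index = 1L, first_trial_id = 1L) {
  if (n == 0L) return(sample_trial(config, condition)[0, ])
  data.table::rbindlist(lapply(seq_len(n), function(i)
    sample_trial(config, condition, trial_id = first_trial_id + i - 1L,
                 block_index = block_index))) |> as.data.frame()
}

#' Analytic expected total reward over one block
#'
#' The task is balanced so that every condition delivers the same expected
#' total reward per 50-trial block (10 ml under defaults). Value-fixed
#' blocks mix the four CS types; ramp blocks take the expectation of the
#' clamped linear ramp evaluated at a uniform stop time (computed by exact
#' piecewise integration, including the clamp at the far value bound).
#'
#' @inheritParams value_at_time
#' @return Expected block reward, ml.
#' @export
expected_block_reward <- function(config, condition) {
  vr_check_condition(condition)
  per_trial <- if (condition == "value_fixed") {
    rewards <- c(config$fixed_levels, mean(config$uncertain_reward_interval))
    sum(config$cs_probability * rewards)
  } else {
    a <- config$stop_window[1]
    b <- config$stop_window[2]
    rho <- config$ramp_rate / 1000            # ml per ms
    span <- config$value_max - config$value_min
    tstar <- min(max(span / rho, a), b)       # time the clamp engages
    if (condition == "value_increase") {
      # integral of (vmin + rho t) on [a, tstar], vmax on [tstar, b]
      (config$value_min * (tstar - a) + rho * (tstar^2 - a^2) / 2 +
         config$value_max * (b - tstar)) / (b - a)
    } else {
      (config$value_max * (tstar - a) - rho * (tstar^2 - a^2) / 2 +
         config$value_min * (b - tstar)) / (b - a)
    }
  }
  config$block_size * per_trial
}
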