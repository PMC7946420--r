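cfg <- task_config()

test_that("fit_time_slope is exact on noiseless lines and degenerate input", {
  centers <- seq(750, 2350, by = 200)
  bins <- data.frame(center_ms = centers, rate = 3:11)
  f <- fit_time_slope(bins)
  expect_equal(f$slope, 5)  # 1 spike/s per 0.2 s bin
  expect_equal(f$p_value, 0)
  expect_equal(f$n_bins, 9)
  flat <- fit_time_slope(data.frame(center_ms = centers, rate = rep(4, 9)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)
  few <- fit_time_slope(data.frame(center_ms = centers,
                                   rate = c(1, 2, rep(NA, 7))))
  expect_false(few$usable)
  # cross-check a noisy fit against lm()
  set.seed(61)
  y <- 3 + 1.2 * centers / 1000 + rnorm(9, 0, 0.5)
  f2 <- fit_time_slope(data.frame(center_ms = centers, rate = y))
  ref <- summary(lm(y ~ I(centers / 1000)))$coefficients
  expect_equal(f2$slope, ref[2, 1], tolerance = 1e-10)
  expect_equal(f2$p_value, ref[2, 4], tolerance = 1e-10)
})

test_that("cue regression recovers an exact line over value levels", {
  # construct a session whose rates are exactly linear in the cued level
  trials <- do.call(rbind, lapply(1:30, function(i) {
    tr <- sample_trial(cfg, "value_fixed", trial_id = i)
    tr$cs_type <- c("fixed_small", "fixed_medium", "fixed_large")[
      (i - 1) %% 3 + 1]
    tr$reward_ml <- c(0.1, 0.2, 0.3)[(i - 1) %% 3 + 1]
    tr$stop_time_ms <- NA_real_; tr$stop_onset_ms <- NA_real_
    tr
  }))
  lvl <- rep_len(1:3, nrow(trials))
  # 5 * level spikes in the 300 ms cue window -> rate 16.67 per level step
  sp <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    n_sp <- 5L * lvl[i]
    data.frame(neuron_id = 1L, trial_id = trials$trial_id[i],
               spike_time_ms = trials$cs_onset_ms[i] + 100 +
                 seq_len(n_sp) * 290 / n_sp)
  }))
  s <- session_data(trials, sp, config = cfg)
  f <- fit_value_regression_cue(s, 1L)
  expect_equal(f$coefficient, 5 / 0.3)
  expect_equal(f$p_value, 0)
  fml <- fit_value_regression_cue(s, 1L, value_coding = "ml")
  expect_equal(fml$coefficient, 5 / 0.3 / 0.1)
  # a missing level is a named error
  s2 <- s
  s2$trials <- s2$trials[s2$trials$cs_type != "fixed_medium", ]
  s2$spikes <- s2$spikes[s2$spikes$trial_id %in% s2$trials$trial_id, ]
  expect_error(fit_value_regression_cue(s2, 1L), "fixed_medium")
})

test_that("stop regression reproduces closed-form three-point OLS", {
  set.seed(62)
  trials <- do.call(rbind, lapply(1:30, function(i)
    sample_trial(cfg, "value_decrease", trial_id = i)))
  # force known group means: rewards at group centers
  trials$reward_ml <- rep(c(0.13, 0.195, 0.265), each = 10)
  trials$stop_time_ms <- (cfg$value_max - trials$reward_ml) /
    cfg$ramp_rate * 1000
  trials$stop_onset_ms <- trials$cs_onset_ms + trials$stop_time_ms
  # rates exactly 2, 4, 6 spikes/s in the 350 ms stop window per group
  counts <- round(c(2, 4, 6) * 0.35)  # 1, 1, 2 spikes... use rate via reps
  sp <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    g <- (i - 1) %/% 10 + 1
    n_sp <- c(7, 14, 21)[g]  # 20, 40, 60 spikes/s
    data.frame(neuron_id = 1L, trial_id = trials$trial_id[i],
               spike_time_ms = trials$stop_onset_ms[i] + 150 +
                 seq_len(n_sp) * 340 / n_sp)
  }))
  s <- session_data(trials, sp, config = cfg)
  f <- fit_value_regression_stop(s, 1L, "value_decrease")
  x <- c(1.3, 1.95, 2.65)
  y <- c(7, 14, 21) / 0.35
  beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(f$coefficient, beta_hat)
  expect_equal(f$groups$n, c(10L, 10L, 10L))
  # identical group rates give coefficient 0
  sp2 <- sp; g_all <- rep(1:3, each = 10)
  sp2 <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i)
    data.frame(neuron_id = 1L, trial_id = trials$trial_id[i],
               spike_time_ms = trials$stop_onset_ms[i] + 150 +
                 seq_len(7) * 340 / 7)))
  s2 <- session_data(trials, sp2, config = cfg)
  expect_equal(fit_value_regression_stop(s2, 1L,
                                         "value_decrease")$coefficient, 0)
  # an empty value group is a descriptive error
  s3 <- s
  s3$trials$reward_ml[s3$trials$reward_ml < 0.16] <- 0.2
  expect_error(fit_value_regression_stop(s3, 1L, "value_decrease"),
               "occupancy")
  expect_error(fit_value_regression_stop(s, 1L, "value_fixed"),
               "ramp condition")
})

test_that("compare_two_slopes behaves at the extremes and under the null", {
  f <- list(slope = 1.2, slope_se = 0.3)
  same <- compare_two_slopes(f, f)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  apart <- compare_two_slopes(list(slope = 5, slope_se = 0.01),
                              list(slope = -5, slope_se = 0.01))
  expect_lt(apart$p_value, 1e-6)
  expect_error(compare_two_slopes(list(slope = 1, slope_se = 0),
                                  list(slope = 2, slope_se = 0)),
               "zero combined")
  # null calibration on synthetic slope pairs
  set.seed(63)
  p <- replicate(2000, {
    a <- rnorm(1, 0, 0.3); b <- rnorm(1, 0, 0.3)
    compare_two_slopes(list(slope = a, slope_se = 0.3),
                       list(slope = b, slope_se = 0.3))$p_value
  })
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("gaze-rate correlation finds dependence only when present", {
  set.seed(64)
  cfg2 <- task_config(block_order = "value_increase")
  neurons <- list(neuron_ground_truth(1L, baseline_rate = 5,
                                      tonic_mode = "mixed"))
  neurons[[1]]$class <- "null"
  s <- simulate_population(cfg2, neurons = neurons, n_blocks = 2,
                           gaze = TRUE, seed = 64)
  gc <- suppressMessages(gaze_rate_correlation(s, 1L, "value_increase"))
  ok <- !is.na(gc$r)
  expect_gt(sum(ok), 3)
  expect_true(all(abs(gc$r[ok]) < 0.6))
  expect_false(any(gc$p_value[ok] < 0.001, na.rm = TRUE))
  # perfect dependence: rebuild spikes as an affine function of gaze
  gz <- s$gaze
  tr <- s$trials[s$trials$condition == "value_increase" &
                   s$trials$aborted == 0, ]
  sp <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    g <- gz[gz$trial_id == tr$trial_id[i], ]
    t0 <- tr$cs_onset_ms[i] + 650
    ybar <- mean(g$y_deg[g$sample_time_ms >= t0 &
                           g$sample_time_ms < t0 + 200])
    n_sp <- max(0, round(10 + 50 * ybar))
    if (n_sp == 0) return(NULL)
    data.frame(neuron_id = 2L, trial_id = tr$trial_id[i],
               spike_time_ms = t0 + seq_len(n_sp) * 199 / n_sp)
  }))
  s$spikes <- rbind(s$spikes, sp)
  s$trials$stop_time_ms[match(tr$trial_id, s$trials$trial_id)] <- 2450
  gc2 <- suppressMessages(gaze_rate_correlation(s, 2L, "value_increase"))
  expect_gt(gc2$r[1], 0.8)
  # degenerate: constant gaze leaves bins flagged
  s$gaze$y_deg <- 1
  gc3 <- suppressMessages(gaze_rate_correlation(s, 2L, "value_increase"))
  expect_true(all(is.na(gc3$r)))
  expect_error(gaze_rate_correlation(tiny_session(), 1L, "value_increase"),
               "no gaze")
})

test_that("bootstrap mode comparison handles ties, dominance and nulls", {
  periods <- c("initial", "middle", "late")
  base <- expand.grid(neuron_id = 1:19, period = periods,
                      stringsAsFactors = FALSE)
  # exact ties are never significant
  tie <- transform(base, delta_non_burst = 1.5, delta_burst = 1.5)
  bt <- bootstrap_mode_comparison(tie, seed = 1)
  expect_true(all(bt$count_tie == 1000))
  expect_false(any(bt$significant))
  # deterministic dominance: count 1000, direction non_burst
  dom <- transform(base, delta_non_burst = rnorm(nrow(base)) + 10,
                   delta_burst = rnorm(nrow(base)))
  bt2 <- bootstrap_mode_comparison(dom, seed = 1)
  expect_true(all(bt2$count_non_burst_larger == 1000))
  expect_true(all(bt2$significant))
  expect_true(all(bt2$direction == "non_burst"))
  # determinism under seed; neurons with missing data are excluded
  dom$delta_burst[3] <- NA
  expect_message(bt3 <- bootstrap_mode_comparison(dom, seed = 5),
                 "excluding 1")
  expect_equal(bt3$n_neurons, rep(18L, 3))
  bt4 <- suppressMessages(bootstrap_mode_comparison(dom, seed = 5))
  expect_identical(bt3, bt4)
  expect_error(bootstrap_mode_comparison(tie[0, ]), "no neurons")
})

test_that("logistic choice fit recovers parameters and flags separation", {
  set.seed(65)
  ch <- simulate_choice_sessions(cfg, beta0 = 0, beta1 = 10,
                                 n_trials = 5000)
  f <- fit_choice_logistic(ch)
  expect_equal(f$beta1, 10, tolerance = 3 * f$se1 / 10)
  expect_lt(abs(f$beta0), 3 * f$se0 + 0.05)
  # agreement with a brute-force likelihood grid on a small instance
  ch2 <- ch[1:40, ]
  f2 <- fit_choice_logistic(ch2)
  grid_b1 <- seq(-80, 80, by = 0.25)
  nll <- vapply(grid_b1, function(b1) {
    eta <- f2$beta0 + b1 * (ch2$v_right - ch2$v_left)
    -sum(ch2$choice_right * eta - log1p(exp(eta)))
  }, numeric(1))
  expect_equal(f2$beta1, grid_b1[which.min(nll)], tolerance = 0.3)
  # complete separation errors, penalized fallback works
  sep <- data.frame(v_right = c(0.1, 0.1, 0.3, 0.3),
                    v_left = c(0.3, 0.3, 0.1, 0.1),
                    choice_right = c(0L, 0L, 1L, 1L))
  expect_error(fit_choice_logistic(sep), "separation")
  fp <- fit_choice_logistic(sep, penalized = TRUE)
  expect_true(is.finite(fp$beta1) && fp$beta1 > 0)
  expect_error(fit_choice_logistic(
    data.frame(v_right = 0.2, v_left = 0.1, choice_right = 1L)),
    "both outcomes")
})

test_that("per-session choice slopes reject zero under a positive rule", {
  # mirrors the population-level test of choice behaviour: fit one slope
  # per simulated session, then a Wilcoxon signed-rank across sessions
  set.seed(67)
  b1 <- replicate(20, fit_choice_logistic(
    simulate_choice_sessions(cfg, beta0 = 0, beta1 = 5,
                             n_trials = 300))$beta1)
  expect_lt(wilcox.test(b1, mu = 0)$p.value, 0.001)
})

test_that("classify_neuron flags a strong tonic increaser and not a null", {
  s <- tiny_session()
  cs <- suppressMessages(summarize_population(s))
  expect_equal(nrow(cs), 2)
  row1 <- cs[cs$neuron_id == 1, ]
  expect_gt(row1$slope_increase, 0)
  expect_true(row1$tonic_increaser)
  expect_false(cs$tonic_decreaser[cs$neuron_id == 1])
})

test_that("population correlations reflect constructed dependence", {
  set.seed(66)
  n <- 60
  fake <- data.frame(neuron_id = 1:n,
                     slope_increase = rnorm(n),
                     slope_decrease = rnorm(n),
                     stop_coef_increase = rnorm(n),
                     stop_coef_decrease = rnorm(n))
  fake$cue_coef <- fake$slope_increase * 0.9 + rnorm(n, 0, 0.3)
  pc <- population_correlations(fake)
  r1 <- pc[pc$var_x == "slope_increase" & pc$var_y == "cue_coef", ]
  expect_gt(r1$r, 0.5)
  expect_lt(r1$p_value, 0.001)
  r2 <- pc[pc$var_x == "slope_increase" &
             pc$var_y == "stop_coef_increase", ]
  expect_lt(abs(r2$r), 0.35)
})
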