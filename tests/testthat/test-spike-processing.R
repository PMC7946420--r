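test_that("align_spikes subtracts event times and skips eventless trials", {
  s <- tiny_session()
  sp1 <- s$spikes[s$spikes$neuron_id == 1L, ]
  al <- align_spikes(s, 1L, "cs_onset")
  tr <- s$trials
  ev <- tr$cs_onset_ms[match(al$trial_id, tr$trial_id)]
  back <- al$t_rel + ev
  expect_setequal(round(back, 9), round(sp1$spike_time_ms, 9))
  # stop alignment drops value-fixed trials (no stop event)
  expect_message(al2 <- align_spikes(s, 1L, "stop_onset"), "skipped")
  expect_equal(attr(al2, "n_skipped"),
               sum(tr$condition == "value_fixed" & tr$aborted == 0))
  expect_true(all(al2$trial_id %in%
                    tr$trial_id[tr$condition != "value_fixed"]))
})

test_that("truncate_at_stop removes post-stop spikes and keeps horizons", {
  s <- tiny_session()
  al <- align_spikes(s, 1L, "cs_onset", conditions = "value_increase")
  tru <- truncate_at_stop(al, s$trials)
  h <- attr(tru, "horizons")
  expect_true(all(tru$t_rel < h[as.character(tru$trial_id)]))
  # manual check on a constructed pair of spikes
  fake <- data.frame(trial_id = c(1, 1), t_rel = c(800, 1200))
  attr(fake, "trials") <- 1
  tr <- data.frame(trial_id = 1, stop_time_ms = 1000)
  out <- truncate_at_stop(fake, tr)
  expect_equal(out$t_rel, 800)
  # stop at the window end removes nothing
  tr$stop_time_ms <- 2450
  expect_equal(nrow(truncate_at_stop(fake, tr)), 2)
  # mean retained horizon tracks the mean stop time
  expect_equal(mean(h[is.finite(h)]),
               mean(s$trials$stop_time_ms[s$trials$condition ==
                                            "value_increase"],
                    na.rm = TRUE))
})

test_that("SDF kernel is unit-area and peaks at the closed-form value", {
  one <- data.frame(trial_id = 1L, t_rel = 0)
  attr(one, "trials") <- 1L
  sdf <- compute_sdf(one, grid = seq(-100, 100, by = 1), kernel_sigma = 15)
  expect_equal(sdf$rate[sdf$time_ms == 0], 1000 / (15 * sqrt(2 * pi)),
               tolerance = 1e-9)
  expect_equal(sum(sdf$rate) / 1000, 1, tolerance = 1e-6)
  # no spikes -> zero SDF (still per-trial averaged)
  none <- data.frame(trial_id = integer(0), t_rel = numeric(0))
  attr(none, "trials") <- 1L
  sdf0 <- compute_sdf(none, grid = seq(0, 10, by = 1))
  expect_true(all(sdf0$rate == 0))
  # zero-trial request is an error, not a silent zero
  attr(none, "trials") <- integer(0)
  expect_error(compute_sdf(none), "zero-trial")
})

test_that("truncation-aware averaging uses per-point trial counts", {
  al <- data.frame(trial_id = c(1L, 2L), t_rel = c(100, 100))
  attr(al, "trials") <- c(1L, 2L)
  h <- c(`1` = 150, `2` = 1000)
  sdf <- compute_sdf(al, grid = seq(0, 500, by = 1), horizons = h)
  expect_equal(sdf$n_trials[sdf$time_ms == 100], 2)
  expect_equal(sdf$n_trials[sdf$time_ms == 400], 1)
  expect_true(all(diff(sdf$n_trials) <= 0))
  # past the short horizon only trial 2 is averaged, whose kernel mass is
  # negligible at 400 ms (spike at 100 ms, sigma 15 ms)
  expect_equal(sdf$rate[sdf$time_ms == 400], 0)
})

test_that("bin_rates matches brute-force counting under both coverage rules", {
  set.seed(91)
  for (i in 1:300) {
    n_tr <- sample(3:8, 1)
    ids <- seq_len(n_tr)
    stops <- runif(n_tr, 400, 2450)
    sp <- data.frame(
      trial_id = rep(ids, each = 30),
      t_rel = runif(30 * n_tr, 0, rep(stops, each = 30)))
    attr(sp, "trials") <- ids
    attr(sp, "horizons") <- stats::setNames(stops, ids)
    w <- analysis_windows()
    breaks <- seq(650, 2450, by = 200)
    if (all(stops < breaks[2])) {
      # no trial covers even the first bin: the documented error contract
      expect_error(bin_rates(sp, w), "all bins missing")
      next
    }
    br <- bin_rates(sp, w)
    for (b in seq_len(9)) {
      cov <- ids[stops >= breaks[b + 1]]
      if (!length(cov)) {
        expect_true(is.na(br$rate[b]))
      } else {
        inb <- sp$trial_id %in% cov & sp$t_rel >= breaks[b] &
          (if (b == 9) sp$t_rel <= breaks[b + 1] else sp$t_rel <
             breaks[b + 1])
        expect_equal(br$rate[b], sum(inb) / length(cov) / 0.2)
      }
    }
    # partial coverage: total count over total exposure
    bp <- bin_rates(sp, w, coverage = "partial")
    expo <- sum(pmax(pmin(stops, 850) - 650, 0)) / 1000
    cnt <- sum(sp$t_rel >= 650 & sp$t_rel < 850)
    expect_equal(bp$rate[1], cnt / expo)
  }
})

test_that("whole-bin coverage enumerates valid bins for a common stop", {
  sp <- data.frame(trial_id = c(1L, 1L), t_rel = c(700, 980))
  attr(sp, "trials") <- 1L
  attr(sp, "horizons") <- c(`1` = 1000)
  br <- bin_rates(sp, analysis_windows())
  expect_equal(sum(!is.na(br$rate)), 1L)  # only [650, 850) is covered
  expect_equal(br$rate[1], 1 / 0.2)
  expect_true(all(is.na(br$rate[-1])))
  # empty spike set with full coverage -> all bins zero
  sp0 <- data.frame(trial_id = integer(0), t_rel = numeric(0))
  attr(sp0, "trials") <- 1L
  attr(sp0, "horizons") <- c(`1` = Inf)
  expect_true(all(bin_rates(sp0, analysis_windows())$rate == 0))
})

test_that("baseline_rate recovers the generator baseline", {
  s <- tiny_session()
  lam0 <- s$ground_truth$baseline_rate[2]
  n_tr <- sum(s$trials$aborted == 0)
  est <- baseline_rate(s, 2L)
  se <- sqrt(lam0 / (0.5 * n_tr))  # Poisson-scale bound on the SE
  expect_equal(est, lam0, tolerance = 3 * se / lam0)
  expect_error(baseline_rate(s, 2L, conditions = "no_such"),
               "no valid trials")
})

test_that("saccade detector finds injected saccades and ignores noise", {
  tr <- data.frame(reward_onset_ms = 4250, cs_onset_ms = 1400)
  set.seed(5)
  quiet <- simulate_gaze(tr, noise_sd = 0.05)
  expect_length(detect_saccades(quiet), 0)
  sac <- data.frame(onset_ms = c(1200, 2600), amplitude_deg = 6,
                    duration_ms = 40)
  gz <- simulate_gaze(tr, sac, noise_sd = 0.05)
  det <- detect_saccades(gz)
  expect_length(det, 2)
  expect_true(all(abs(det - sac$onset_ms) <= 2 * 1000 / 240 + 1e-9))
  # amplitude 0 and supra-max thresholds produce no detections
  gz0 <- simulate_gaze(tr, data.frame(onset_ms = 1200, amplitude_deg = 0,
                                      duration_ms = 40), noise_sd = 0.05)
  expect_length(detect_saccades(gz0), 0)
  expect_length(detect_saccades(gz, velocity_threshold = 1e5), 0)
  # irregular sampling is rejected
  bad <- quiet
  bad$sample_time_ms[10] <- bad$sample_time_ms[10] + 2
  expect_error(detect_saccades(bad), "irregular")
  expect_error(detect_saccades(data.frame(sample_time_ms = c(0, 1, 1),
                                          x_deg = 0, y_deg = 0)),
               "strictly increasing")
})

test_that("detector recovers >=99% of strong saccades, none in noise", {
  set.seed(6)
  tr <- data.frame(reward_onset_ms = 4250)
  hits <- 0; n_inj <- 0; false_pos <- 0
  for (i in 1:50) {
    onset <- runif(1, 500, 3800)
    gz <- simulate_gaze(tr, data.frame(onset_ms = onset, amplitude_deg = 6,
                                       duration_ms = 40), noise_sd = 0.1)
    det <- detect_saccades(gz)
    n_inj <- n_inj + 1
    if (any(abs(det - onset) < 50)) hits <- hits + 1
    false_pos <- false_pos + length(detect_saccades(
      simulate_gaze(tr, noise_sd = 0.1)))
  }
  expect_gte(hits / n_inj, 0.99)
  expect_equal(false_pos, 0)
})
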