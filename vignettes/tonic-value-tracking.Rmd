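---
title: "Methods: analysing tonic value tracking in dopamine spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing tonic value tracking in dopamine spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valueramp)
```

## The problem

Midbrain dopamine neurons are classically described through short-latency
*phasic* bursts that signal reward prediction errors. `valueramp` implements
the analysis pipeline for a complementary question: do these neurons also
track a *continuously changing* reward value with a sustained, tonic change
in firing rate?

The experimental design the package models is a Pavlovian task with three
blocked conditions. A conditioned stimulus (CS) is shown for 2850 ms and the
reward it cues either

* **value-increase** — ramps up from 0.1 ml at 0.082 ml/s,
* **value-decrease** — ramps down from 0.3 ml at the same rate, or
* **value-fixed** — stays constant (0.1, 0.2 or 0.3 ml, or an "uncertain"
  CS paying uniformly 0.1–0.3 ml), each CS type with probability 1/4.

In the ramp conditions the ramp halts at a *stop time* drawn uniformly on
0–2450 ms after CS onset, which fixes the trial's reward at the value
reached at that moment. The design is balanced: every 50-trial block pays
10 ml in expectation. Because the ramp rate is constant, *value* and
*elapsed time* are confounded within one ramp condition but dissociated
between the two (value rises with time in one, falls in the other) — the
key to interpreting a tonic rate change as value tracking rather than
timing.

## The analysis chain

All operations work on a `session_data` container (trial table + spike
table, optional gaze/lick tables). Times are milliseconds within a trial;
analyses align spikes to a named event (fixation onset, CS onset, ramp
stop).

1. **Spike density functions** (`compute_sdf`): every spike is replaced by
   a unit-area Gaussian with $\sigma = 15$ ms, evaluated on a 1 ms grid,
   giving rates in spikes/s. The kernel is symmetric (non-causal) and
   un-truncated; only $\sigma$ is a modelling constant.
2. **Stop truncation** (`truncate_at_stop`): for CS-aligned analyses of the
   ramp conditions, only spikes emitted while the value was still changing
   are used. Each trial keeps a *valid horizon* (its stop time); averaged
   SDFs divide, at every grid point, only by the trials whose horizon
   covers that point, and a spike's kernel never extends past its own
   trial's horizon.
3. **Baseline** (`baseline_rate`): mean rate 500–0 ms before fixation
   onset, subtracted for population averages and the firing-mode
   comparison.
4. **Tonic slope** (`bin_rates` + `fit_time_slope`): the window 650–2450 ms
   after CS onset (set to exclude the phasic CS response) is divided into
   nine 200 ms bins; the across-trial mean rate per bin is regressed on the
   bin-center time in seconds (OLS, two-sided t test). Slopes are in
   spikes/s per s.
5. **Phasic value coding** (`fit_value_regression_cue`,
   `fit_value_regression_stop`): trial rates 100–400 ms after CS onset
   regressed on the cued value (value-fixed condition, uncertain CS
   excluded), and group-mean rates 150–500 ms after the stop regressed on
   the group-mean reward of the small (0.1–0.16 ml), medium (0.16–0.23 ml)
   and large (0.23–0.3 ml) trial groups. The default value coding is
   *levels of 0.1 ml* (1, 2, 3): printed regression coefficients of this
   size are only consistent with a coarse value unit, and the coding
   rescales coefficients without touching significance.
6. **Burst classification** (`label_bursts`): the classical ISI criteria —
   an ISI ≤ 80 ms opens a burst, the burst ends at the first ISI > 160 ms.
   Intermediate ISIs (80–160 ms) extend an ongoing burst but cannot open
   one; boundary values follow the wording "80 ms or less" and "more than
   160 ms". Labeling never crosses trial boundaries, because inter-trial
   gaps make ISIs unreliable.
7. **Firing-mode bootstrap** (`mode_period_deltas` +
   `bootstrap_mode_comparison`): per neuron, baseline-subtracted rates of
   burst and non-burst spikes in the initial (650–1250 ms), middle
   (1250–1850 ms) and late (1850–2450 ms) periods; neurons are resampled
   with replacement 1000 times and the population means of the two modes
   compared; one sign in more than 975 repetitions is significant
   (two-sided p < 0.05). Ties count toward neither sign (measure zero with
   continuous rates).
8. **Choice behaviour** (`fit_choice_logistic`):
   $P(\text{right}) = 1/(1+e^{-(\beta_0+\beta_1 (V_R - V_L))})$, fit by
   maximum likelihood; with a single predictor, complete separation is
   detected exactly as non-overlap of the $V_R-V_L$ ranges of the two
   outcomes and reported as an error (an L2-penalised fit is available
   behind `penalized = TRUE`).
9. **Classification** (`classify_neuron`): a neuron is a *tonic increaser*
   if its value-increase slope is positive with p < 0.05, a *tonic
   decreaser* if its value-decrease slope is negative with p < 0.05;
   value-coder flags use the regression coefficients at p < 0.05. Raw
   p-values are reported without multiplicity correction, matching the
   original analysis; a Benjamini–Hochberg column can be added downstream
   but is deliberately not part of the summary.

### Numerical and design choices

* **Whole-bin coverage.** A truncated trial contributes to a 200 ms bin
  only if its stop time covers the entire bin, avoiding partial-bin rate
  bias. Under continuous uniform stop times no trial covers a bin ending
  at 2450 ms, so slope fits typically use eight of the nine bins. For the
  600 ms periods of the firing-mode comparison the same rule would leave
  the late period empty with probability one; period rates therefore use
  the exposure-weighted (partial-coverage) rule, available in `bin_rates`
  via `coverage = "partial"`.
* **Calibration of the slope test.** On constant-rate (null) neurons with
  full coverage the OLS t test is nominal (measured 4.6% at
  $\alpha = 0.05$ over 1000 simulated nulls). Under stop truncation the
  late bins average over few trials and sit at high leverage, which
  inflates the test to roughly 8% for any constant-rate neuron — a
  property of the binning-plus-OLS method under this task design, not of
  the implementation. The package reports the method's raw p-values; the
  one-sided classification flags consequently run at roughly 4% per
  direction.
* **Mode-specific baselines.** The baseline subtracted from burst
  (non-burst) rates is computed from the burst (non-burst) spikes of the
  same neuron in the pre-fixation window; the pooled-baseline alternative
  is available via `baseline = "overall"` in `mode_period_deltas`.
* **Degenerate fits.** Noise-free regressions (zero residual variance)
  return p = 1 for a zero slope and p = 0 otherwise; fits with fewer than
  three usable bins are flagged unusable and excluded from population
  summaries.
* **Saccade detection.** Angular velocity is taken by central differences
  over a ±2-sample span after a 3-sample running median and a 5-sample
  moving average of position; onsets are the first sample of each run
  above 40°/s, runs closer than 50 ms are merged. The smoothing constants
  are chosen so that the 0.2° positional jitter of the synthetic gaze
  traces at 240 Hz stays well below threshold (zero false detections)
  while the zero-phase filters keep onset timing within about two samples.

## The synthetic world

No recordings ship with the package; `simulate_population` generates
sessions with the statistical structure the analysis assumes, with ground
truth retained for white-box tests.

Each neuron fires as the superposition of:

* a **smooth component** — baseline rate $\lambda_0$ (drawn uniformly from
  3–5 spikes/s, matching the reported baselines of ~3.2–3.8 spikes/s) plus
  a tonic term $g \cdot (v(t) - v(t_{CS}))$ proportional to the *value
  change* since CS onset (not to elapsed time, preserving the design's
  value/time dissociation), floored at zero. It is generated as an
  inhomogeneous renewal process by time-rescaling Erlang-$k$ intervals
  through the integrated intensity, with an equilibrium (stationary)
  start. `tonic_mode = "non_burst_dominant"` uses $k = 20$ (ISI CV ≈ 0.22,
  the regular, pacemaker-like regime described for dopamine neurons):
  at all realized rates (≤ ~9 spikes/s) tonic ISIs then rarely reach the
  80 ms burst criterion, so the tonic ramp is carried by non-burst spikes.
  With $k = 1$ the process is exactly an inhomogeneous Poisson process
  (used for the phasic-only and unmodulated classes). A lower $k$ (e.g. 6)
  was rejected because its burst-onset probability grows steeply with
  rate, letting the burst subtrain inherit the tonic ramp and
  contradicting the non-burst-dominant contract.
* **phasic components** — rectangular intensity bumps spanning exactly the
  measurement windows (100–400 ms after CS onset, scaled by the cued value
  level; 150–500 ms after the stop, scaled by the trial's value level,
  positive when a value decrease halts and negative when an increase
  halts), drawn as an inhomogeneous Poisson process. A fraction
  `burst_fraction` of phasic spikes seeds a burst of ≥ 2 spikes with
  intra-burst ISIs of 15–60 ms, detectable by construction under the
  80/160 ms criteria.

A 3 ms absolute refractory period is applied to the merged train. Every
spike carries a provenance tag (baseline / tonic / phasic / burst member)
in a debug table that only white-box tests read.

Two consequences are worth stating plainly:

* **Phasic gains are seed rates.** Burst expansion multiplies the realized
  phasic spike count by roughly $1 + \text{burst\_fraction} \times
  (\text{mean burst size} - 1)$ and smears mass slightly past the kernel
  window. Parameter-recovery tests therefore use `burst_fraction = 0`
  neurons, for which the generative gain equals the regression coefficient
  being recovered.
* **What a green test establishes.** The generator realizes the rate
  structure, burst structure, task timing, behavioural couplings and
  non-couplings the analysis assumes — and nothing more. It does not model
  spike waveforms, recording drift, cross-trial dependencies, eye-blink
  artifacts, or correlated lick/gaze–rate couplings; green tests certify
  the pipeline's estimators and their calibration on this stated world,
  not biological fidelity of the simulation.

Gaze traces are 240 Hz with Gaussian positional jitter (SD 0.2°) and
minimum-jerk saccades along the vertical bar axis; licks are a homogeneous
Poisson process independent of firing (so lick-aligned SDFs are flat by
construction — an explicit independence null, since no distributional
detail about licking is available); choice sessions draw both stimulus
values uniformly on 0.1–0.3 ml and choices from the logistic rule.

The stop-time distribution is continuous uniform (a 1 ms quantisation is
available via `quantize_stop_ms`); the uncertain-CS reward is continuous
uniform on 0.1–0.3 ml; aborted trials can be injected at a configurable
rate (default 0) and are re-drawn rather than recycled. Trial time starts
1000 ms before fixation onset so that the 500 ms pre-fixation baseline
window lies inside the recorded interval.

## Reproducibility

All sampling flows through R's global RNG; `simulate_population`,
`run_study` and the CLI take explicit seeds, and `run_study` derives
per-stage seeds from the master seed so stages can be re-run in isolation.
Identical config and seed give byte-identical CSV outputs. The study
configuration (task constants, windows, burst criteria, bootstrap
settings, population counts) is one JSON document; its hash is recorded in
every session manifest.

## Known limitations

* The slope regression fits across-trial mean bin rates (one point per
  bin); a trial-level mixed-effects alternative is out of scope.
* Population SDFs in ramp conditions average over a shrinking trial count
  at late times; `n_trials` is exposed per grid point rather than
  committing to a renormalisation convention.
* The bootstrap's neuron-resampling scheme treats neurons as exchangeable
  and ignores within-neuron estimation error, exactly as the original
  procedure does; its false-positive rate measured under a null generator
  is ~7%, slightly above the nominal 5%.
* The printed scale of published slope statistics (per second vs per bin)
  is ambiguous; this package reports spikes/s per s throughout.
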