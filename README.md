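# valueramp

Spike-train analysis of tonic dopamine activity tracking gradual
reward-value changes.

## What this package is for

Phasic dopamine bursts are the textbook carrier of reward prediction
errors. `valueramp` implements, as a tested and reusable R pipeline, the
complementary analysis: detecting a *tonic* firing mode that follows a
reward value while it is still changing. The experimental design it models
is a Pavlovian task in which a conditioned stimulus (CS) cues a reward
that, within a trial, either ramps up from 0.1 ml at 0.082 ml/s, ramps
down from 0.3 ml, or stays fixed; in the ramp conditions the ramp halts at
a stop time uniform on 0–2450 ms after CS onset, fixing the trial's
reward. The package is aimed at systems/computational neuroscientists who
want to run, audit, or extend this analysis on their own trial-based
spike data — or validate it end to end on synthetic data with known ground
truth.

The statistical core, in the field's standard notation:

* spike density functions by Gaussian-kernel smoothing
  (σ = 15 ms), baseline-subtracted (baseline = rate 500–0 ms before
  fixation onset), with stop-time truncation and coverage-aware averaging;
* the tonic slope: OLS of mean firing rate in nine 200 ms bins spanning
  650–2450 ms after CS onset on bin-center time — a *tonic increaser* has
  slope > 0 at p < 0.05;
* phasic value regressions: trial rate 100–400 ms after CS onset on cued
  value (value-fixed condition), and group-mean rate 150–500 ms after the
  ramp stop on group-mean reward (small/medium/large value groups);
* burst/non-burst classification by the classical ISI criteria (burst
  opens at ISI ≤ 80 ms, ends at ISI > 160 ms), and a neuron-resampling
  bootstrap (1000 repetitions, >975 of one sign significant) comparing
  baseline-subtracted rates of the two firing modes over the
  initial/middle/late thirds of the tonic window;
* the psychometric choice model
  P(right) = 1 / (1 + exp(−(β₀ + β₁(V_right − V_left)))).

A fully seeded generator (`simulate_population`) produces spike trains
(inhomogeneous renewal/Poisson with burst expansion), gaze traces, lick
events and choice behaviour with ground-truth labels, so every stage is
testable without recorded data. See the methods vignette
(`vignettes/tonic-value-tracking.Rmd`) for models, assumptions and design
choices.

## Worked example

Simulate a 99-neuron study (19 tonic increasers, 15 tonic decreasers, 30
phasic-only, 35 unmodulated neurons; one 50-trial block per condition) and
analyse it:

```r
library(valueramp)
cfg <- read_study_config()          # package defaults
rep <- run_study(cfg, seed = 1, out_dir = "demo_out")
print(rep)
```

```
<study_report> seed 1
 neurons: 99 | tonic increasers: 14 | tonic decreasers: 9
 cue value coders: 35 | trials: 150 (aborted 0)
 firing-mode bootstrap:
   period count_non_burst_larger count_burst_larger significant
1 initial                   1000                  0        TRUE
2  middle                   1000                  0        TRUE
3    late                    991                  9        TRUE
```

Reading the output: 14 of the 19 generated tonic increasers and 9 of the
15 decreasers are recovered at p < 0.05 from a single 50-trial block per
condition (single-block power; with two blocks recovery is near-complete),
and the firing-mode bootstrap attributes the tonic ramp to non-burst
spikes in all three periods — the qualitative signature the analysis is
designed to expose. `demo_out/` contains the session CSVs
(`trials.csv`, `spikes.csv`, ground truth, manifest with config hash), the
per-neuron `neuron_summary.csv` (slopes, coefficients, p-values, flags),
`correlations.csv` (tonic-phasic population correlations) and
`bootstrap.csv`.

Individual stages are plain functions on plain tables:

```r
s   <- simulate_population(task_config(), seed = 7)
al  <- align_spikes(s, neuron_id = 1, "cs_onset",
                    conditions = "value_increase")
tru <- truncate_at_stop(al, s$trials)
fit_time_slope(bin_rates(tru))   # slope in spikes/s per s, p-value
```

A command-line entry point wraps the same stages:

```sh
Rscript -e 'valueramp::vr_cli()' run --seed 1 --out demo_out
# verbs: generate | analyze | report | run
```

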