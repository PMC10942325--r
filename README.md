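# tachycurve

Chronometric analysis of **urgent saccadic choices** — the toolbox a
psychophysics lab needs to go from per-trial eye-movement records to
tachometric curves, sigmoid-derived rise points, attentional-capture and
motor-bias metrics, and resampling-based inference.

## The problem

In urgent pro/antisaccade tasks the go signal (fixation offset) arrives
*before* the stimuli, by a variable **gap**, so oculomotor plans are already
under way when the informative cue appears. What determines accuracy is not
the reaction time but the **raw processing time**

```
rPT = RT − gap
```

the time the cue was actually visible before the saccade was launched.
Plotting the fraction of correct choices against rPT in sliding bins (the
**tachometric curve**) resolves the perceptual-decision dynamics with
millisecond precision:

* at short rPT (≤ 75 ms) choices are **guesses**, typically biased toward
  the covertly attended cue;
* near rPT ≈ 100 ms, a luminance difference between the stimuli produces
  involuntary **exogenous capture** (a transient deflection toward the
  brighter stimulus, in opposite directions for pro and anti trials);
* later, accuracy rises sigmoidally toward its asymptote as choices become
  **endogenously** informed — about 30 ms later for antisaccades than for
  prosaccades.

The empirical curve is summarised by the sigmoid

```
s(x) = B + (A − B) / (1 + exp(−(x − C) / D))
```

fitted by **mean-absolute-error** minimisation (Nelder–Mead simplex):
`B` baseline, `A` asymptote, `C` the **rise point** (rPT at the halfway
level), `D` the slope scale. A fit qualifies for rise-point analysis when
its modulation-to-error ratio `Δs / e` exceeds 2.5. Confidence intervals
come from bootstrap resampling of trials; group inference uses paired
permutation, randomization, exact binomial, and correlation-permutation
tests.

A built-in generative simulator (`generative_params()`, `generate_trials()`,
`generate_trace()`) emulates the task's statistical structure — biased
guesses, a Gaussian capture bump, the delayed anti rise, 1 kHz minimum-jerk
eye traces — with known ground truth, so every stage supports
parameter-recovery testing without any data download.

## Worked example

```r
library(tachycurve)

params <- generative_params(endo_C_pro = 165, endo_C_anti = 195)
tr     <- generate_trials(params, n = 10000, experiment = 1, seed = 2026)
urgent <- apply_filter(tr, trial_filter(urgency = "urgent_only"))

fit_pro  <- fit_sigmoid(compute_curve(urgent[urgent$trial_type == "pro",  ], bin_width = 31))
fit_anti <- fit_sigmoid(compute_curve(urgent[urgent$trial_type == "anti", ], bin_width = 31))
fit_pro
#> <sigmoid_fit> A=0.934 B=0.543 C=162.9 ms D=17.8 ms (MAE 0.0175; delta_s/e = 22.31, qualifies)
fit_anti
#> <sigmoid_fit> A=0.951 B=0.434 C=195.5 ms D=20.1 ms (MAE 0.0149; delta_s/e = 34.52, qualifies)

antisaccade_cost(fit_pro, fit_anti)
#> <bias_cost> criterion 0.738: anti cost 39.7 ms, motor bias 0.109

guess_bias(urgent)
#> <guess_bias> 1377 toward cue vs 1154 toward non-cue (frac 0.544, rPT <= 75 ms)
```

The fitted rise points recover the planted 165/195 ms within a few ms; the
**antisaccade cost** (39.7 ms here) is the extra processing time the anti
curve needs to reach the shared accuracy criterion (the higher of the two
halfway levels, 0.738); the **motor bias** (0.109) is the difference between
the pro and anti baselines, reflecting guesses drawn toward the attended
cue (54.4% of guesses, above chance).

Raw 1 kHz traces can be scored first (`detect_saccade()` with the 40 °/s
velocity criterion, `score_trial()` with the ±60° near-vertical and blink
exclusions), and a full run is one call:

```r
run_pipeline(out_dir = "out", simulate = list(n = 20000, experiment = 3, seed = 7),
             bright = "cue")
```

or from the shell via `inst/cli/tachy.R`
(`simulate | curve | fit | metrics | report | run-all`).

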