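---
title: "Methods: tachometric analysis of urgent saccadic choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tachometric analysis of urgent saccadic choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tachycurve)
```

## The measurement model

In an urgent pro/antisaccade task the fixation point is extinguished (the
go signal) a variable *gap* before the cue and non-cue appear at ±8°.
Participants saccade toward the cue when it is green (pro) and toward the
non-cue when it is magenta (anti), within a 450 ms deadline. Because the
motor plan starts before the stimulus arrives, the informative quantity is
the raw processing time, `rPT = RT − gap`: the cue-viewing time available
before the saccade. The gap set is
−200, −100, 0, 75, 100, 125, 150, 175, 200, 250, 350 ms; gap < 0 trials
("easy", stimuli visible before the go) are analysed only to define
reliable performers; all substantive analyses use urgent trials
(gap ≥ 0).

The tachometric curve is the fraction of correct choices in rPT bins that
slide every 1 ms (31 ms wide for aggregate curves, 41 ms for single
participants), with exact binomial (Clopper–Pearson) intervals per bin.
Its canonical shape has three regimes: a guessing baseline at short rPT,
an optional transient capture deflection near 100 ms when the stimuli
differ in luminance, and a sigmoidal rise to asymptote as the cue color
informs the choice. The sigmoid

$$ s(x) = B + \frac{A - B}{1 + e^{-(x - C)/D}} $$

is fitted by minimising the mean absolute error over defined bins in
0–300 ms; `C` (the rise point, where `s(C) = (A+B)/2`) marks when the
choice becomes endogenously guided. The baseline `B` is deliberately
*not* fixed at 0.5: uninformed guesses are biased, and that bias is
itself a measurement (`B_pro − B_anti` is the motor bias).

### Headline metrics

* **Rise point / rPT at criterion.** `rpt_at_criterion()` inverts the
  sigmoid in closed form; with θ equal to the halfway level it returns
  `C` exactly.
* **Antisaccade cost.** For a pro/anti fit pair, the shared criterion is
  the *higher* of the two halfway levels; the cost is the difference in
  rPT at which the two fitted curves attain it. Using the higher level
  guarantees both curves are past their own midpoints, where the fits are
  best constrained.
* **Exogenous capture.** Fraction correct inside the fixed 83–124 ms
  window, per trial type, with a randomization test of pro/anti symmetry
  run on the "saccade toward the brighter stimulus" indicator.
  `derive_capture_window()` reconstructs the window from data: the anti
  curve is mirrored about 0.5, the strongest same-sign common deviation
  is located, and the interval is extended to the curves' crossings of
  chance; windows from multiple experiments are intersected. The exact
  crossover-location algorithm used to print 83–124 ms was not specified
  by its source, so the fixed window remains the default for metrics and
  the derived window is validated only for bracketing the capture
  centre.
* **Guessing bias.** Over all trials with rPT ≤ 75 ms, the fraction of
  choices landing on the cue side, regardless of trial type or
  correctness — so an anti-trial *error* counts toward the cue, which is
  what lets pro and anti trials pool.
* **Four-range summary.** G (≤ 75), C (83–124), T (135 ≤ rPT < 200) and
  A (≥ 200) ms; rPTs in (75, 83) or (124, 135) belong to no range. Range
  bounds follow the printed inequalities (inclusive except T's upper
  edge).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `bin_width_aggregate` | 31 | ms | canonical aggregate-curve resolution |
| `bin_width_single` | 41 | ms | single-participant curves need wider bins |
| `bin_step` | 1 | ms | sliding grid |
| `criterion_theta` | 0.7 | — | fixed-accuracy alternative to the rise point |
| `performance_criterion` | 0.7 | — | easy-trial gate, strict, all 8 cells |
| `modulation_ratio_threshold` | 2.5 | — | Δs/e gate for usable fits |
| `capture_window` | [83, 124] | ms | fixed exogenous response window |
| `fit_rpt_range` | [0, 300] | ms | fitting/evaluation support |
| `n_bootstrap` | 1000 | reps | lower end of the canonical 1000–10000 |
| `n_permutations` | 100000 | iters | canonical permutation budget |

Saccade detection uses a 40 °/s velocity criterion on 1 kHz traces.
The differentiator is not dictated by the criterion itself; this package
smooths positions with a 5-sample moving average and uses central
differences (both exposed as arguments). Threshold crossing is *strict*
(> 40 °/s) for deterministic tie handling. Blinks are runs of invalid
samples padded by 25 ms; a blink overlapping [go, onset] excludes the
trial. There is no amplitude exclusion by default; `min_amplitude = 2`
reproduces the robustness check.

## The simulator: what it does and does not emulate

`generate_trials()` draws gap (uniform over the task set), RT (truncated
normal, mean 280, SD 60, support [100, 600] ms — chosen so that rPT
covers the whole 0–300 ms axis across the gap set), trial type and the
block structure (cue side fixed within 150-trial blocks, alternating).
Correctness is sampled first from the planted accuracy model and the
choice side derived from it, so the realised `p(correct | rPT)` is
exactly the planted composition:

* baseline bias 0.56 toward the cue (close to the published pooled
  guessing fraction 9015/16169 ≈ 0.558);
* capture bump amplitude 0.35, centre 100 ms, Gaussian half-width 20 ms —
  an explicit modeling choice: the capture shape is only described
  qualitatively by the literature, and an additive Gaussian is the
  simplest transient with the right support;
* rise points 165 (pro) and 195 (anti) ms, slope scale `D` = 15 ms,
  asymptote 0.93.

Compositions that leave [0, 1] anywhere are rejected at construction
rather than clipped, because clipping would silently distort the planted
curve. The generator does **not** model the post-capture "downward
rebound", sequential dependencies, RT–accuracy coupling beyond the rPT
mechanism, participant heterogeneity within one call, or lapses. A green
parameter-recovery test therefore establishes that the pipeline inverts
*this* generative family, not that real data satisfy it.

`generate_trace()` produces 1 kHz minimum-jerk saccades (8°, 40 ms
duration → ≈ 375 °/s peak) in Gaussian position noise (SD 0.02°). Two
ground-truth onsets are recorded: the kinematic movement start and the
analytic instant the minimum-jerk speed profile crosses 40 °/s (≈ 3.6 ms
later for the default kinematics). Detection accuracy is asserted
against the analytic crossing, because that is what a velocity-criterion
detector estimates; conflating the two would build a ~4 ms bias into the
tests.

## Numerical choices

* **Optimizer.** `stats::optim(method = "Nelder-Mead")` (the fminsearch
  family), `reltol 1e-8`, 2000 iterations, on a transformed space that
  keeps `A, B` in [0, 1] (logit) and `D` in (0, 200] (scaled logit) —
  the raw simplex is unconstrained and fractions must not leave [0, 1].
  Initialisation is data-driven (`B0` = mean fraction below 100 ms,
  `A0` = mean above 250 ms, `C0` = first crossing of the halfway level,
  `D0` = 25 ms) with three seeded jittered restarts; the best objective
  is kept, and results are deterministic given data, init and seed.
* **Objective support.** Bins with zero trials are *undefined*, not
  zero, and are skipped by both the fit objective and the Δs/e average;
  "the 0–300 ms average" is interpreted as over bins where data exist.
* **Bin membership** is closed on both edges (a trial exactly at
  half-width distance counts), for determinism.
* **Flat-fit guard.** A fitted modulation Δs < 0.01 is treated as flat
  (ratio set to 0) instead of risking a spuriously large Δs/e from a
  near-zero denominator on degenerate data.
* **p-value conventions.** Monte-Carlo tests use the +1 correction (the
  observed statistic counts among the permutations), so p ∈ (0, 1];
  exhaustive enumeration replaces sampling automatically whenever the
  full null (2^n sign patterns, n! permutations) fits in the iteration
  budget. The two-sided binomial test uses minimum-likelihood tail
  summation. The published p = 0.033 for a 9-of-11 sign pattern is the
  *one-sided* tail (0.0327; the two-sided value is 0.0654), so the
  sign-consistency analysis here uses `alternative = "greater"`, the
  direction being predicted a priori.
* **Bootstrap.** Percentile (2.5/97.5) intervals; each replicate refits
  from the original solution with a single start (standard for bootstrap
  refits, and what keeps 1000 replicates cheap); failed or degenerate
  replicates are counted and excluded with a warning.

## Known limitations

* The capture-window derivation is a documented reconstruction; with
  strongly biased baselines the per-experiment window can extend well
  beyond the bump until chance is crossed, which is why windows are
  intersected across opposite-luminance experiments and why the fixed
  [83, 124] ms default is used for capture metrics.
* Mean-absolute-error fitting has no closed-form uncertainty; all
  interval statements come from the bootstrap.
* The simulator's RT distribution is stationary; real urgent-task RT
  distributions shift with gap and with practice.
* Blink handling assumes the tracker flags missing samples; no
  velocity-artefact blink reconstruction is attempted.
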