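---
title: "Methods: annotating and simulating shuttling ectotherm temperature traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and simulating shuttling ectotherm temperature traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoshuttle)
```

## The problem

A heliothermic lizard in a shuttle-box setup regulates its body temperature
behaviourally: it basks under a heat source until it reaches an upper
set-point, retreats toward ambient until it reaches a lower set-point, and
repeats. A skin-mounted bio-logger sampling every 2 s at 0.0625 °C
resolution turns each test into a near-continuous skin-temperature trace
(`T_sk`). This package turns such traces into interpretable quantities:
which parts of the test the animal spent thermoregulating, where its upper
and lower set-points lay, how often it shuttled, and how accurately it held
its temperature inside a reference set-point range.

## Section labelling and bouts

Ambient air in the cool refuge sits at a reference temperature `T_a`
(default 18 °C). A sample is **thermoregulating** iff `T_sk > T_a` —
strictly above, so a trace pinned at ambient contains no bouts. A **bout**
is a maximal run of thermoregulating samples. An optional
`min_section_samples` smoothing drops thermoregulating runs shorter than a
minimum length; it is off by default (1 sample) because the measurement
protocol this emulates used none, and it is deliberately one-sided: short
*non*-thermoregulating runs are never relabelled, since a genuine dip to
ambient is informative while a one-sample blip above it is usually noise.

Whether "matching ambient air" should be a band around `T_a` rather than a
single threshold is not determinable from the source material; a single
threshold is used, and measurement noise around ambient therefore flickers
into short empty bouts. These contain no events and do not affect set-point
statistics, but `n_bouts` counts them; use `min_section_samples` if a
cleaner bout count matters.

## Hysteresis set-point detection

Within each bout a three-state machine (unknown / warming / cooling) makes a
single forward pass. It tracks the running extremum of the current segment
and confirms a reversal only when the temperature has moved at least the
**hysteresis** `h` (default 2 °C) back from that extremum: on a confirmed
warming-to-cooling reversal it emits an *upper set-point* at the
running-maximum sample, symmetrically a *lower set-point* at the
running-minimum sample. The hysteresis prevents logger noise (SD ~0.1 °C,
quantization 0.0625 °C) from oversaturating the trace with events.

Numerical conventions, stated once:

* Ties (plateaus are common after quantization) resolve to the **first**
  sample attaining the extremum.
* The initial direction determination from the unknown state is not an event
  and not a direction change.
* A trailing rise or fall that never reverses by `h` before the bout ends
  produces no event, so a terminal extremum is systematically unconfirmed.
* Detector state resets at every bout boundary. Direction changes are
  counted only inside thermoregulating sections; without the reset, the exit
  ramp toward ambient would manufacture an event from the re-entry warming
  of the next bout.
* Thresholds are inclusive (`>= h`), membership is strict (`> T_a`).
* All indices exposed in files and event tables are 0-based; bout ranges are
  half-open `[start, end)`.

An animal is classified a **thermoregulator** iff its total confirmed
direction changes (shuttles) across all bouts exceed two — an animal that
only warmed up once and left stays below the bar.

The detector is verified against an independent brute-force reference (a
quadratic segment-rescanning algorithm in the test helpers) on 1000 random
quantized walks per run, with exact event-index and kind agreement.

## The eight summary statistics

Per trace: mean `T_sk` over the whole test; means of upper and lower
set-point temperatures (absent — never zero — when a kind never occurred);
their difference, the thermal passivity range (TPR); the global maximum
`T_max`; percent of samples thermoregulating; shuttle count; and the
accuracy of thermoregulation **db**: the mean deviation of *all* samples
from a reference range, zero inside the range, distance to the nearest
bound outside. The phrase "deviation from the mean range" admits a scalar
reading (distance to the range midpoint); the range reading is the standard
set-point-range construction and is the default, with the midpoint variant
available as `method = "midpoint"`.

The reference range itself is derived from data
(`derive_reference_range()`): the means of the per-trace upper and lower
set-point means over thermoregulators of a designated baseline (no-wind)
treatment.

A `T_max` at or above a plausibility ceiling (default 41 °C, near the
species' critical thermal maximum — the signature of logger battery drift)
raises a warning flag on the summary. It never drops the trace: exclusion
is an analyst's decision.

## Calibration

Dorsal skin loggers read cooler than cloacal temperature. `fit_offset()`
fits the additive correction only — the source comparison reports a mean
paired difference (1.32 °C, SE 0.247, r = 0.98, n = 14), not a regression —
and `apply_offset()` is opt-in: the pipeline default leaves traces on the
logger scale, and annotation thresholds are never auto-shifted. Hysteresis
detection is translation-invariant, so a joint shift of trace and threshold
leaves events unchanged (tested).

## The synthetic-trace generator

No real traces are distributed, so the simulator *is* the test bed. It
emulates the experiment's stated world: 90 min at 2 s sampling, 0.0625 °C
quantization, 18 °C ambient, a 35 °C basking equilibrium, and no-wind
set-points 34.7 / 29.1 °C.

The latent temperature follows first-order Newtonian heat exchange with a
behaviour-dependent equilibrium, `T'[t+1] = T_env + (T'[t] - T_env) exp(-k dt)`.
Defaults `k_warm = 0.02 s^-1` (heating time constant ~50 s, plausible for a
~3 g animal pressed to a 35 °C tile under a lamp) and `k_cool = 0.003 s^-1`
(passive cooling several times slower while the animal is still in the
heated zone, where the substrate gradient keeps it above ambient). Out of
the heated zone the animal sits on ambient substrate and cools at
`k_rest = 0.02 s^-1`. The controller switches on the **latent** temperature,
keeping behavioural and measurement noise separable; observed temperature is
latent plus Gaussian noise (SD 0.1 °C) quantized to the logger step.
Set-points are re-drawn each shuttle with SD 0.3 °C (clamped to the
physically reachable band below `t_hot`), reproducing realistic set-point
spread.

Two behaviours beyond pure shuttling are needed to reproduce the
experiment's structure, because a pure shuttler never drops below the 18 °C
threshold and would spend ~100% of every test "thermoregulating":

* **Rests**: at each lower set-point, with probability `p_rest` (0.04) the
  animal leaves the heated zone for `rest_s` (360 s) at ambient — the
  source of multi-bout traces.
* **Quitting**: after a per-animal fraction of the test
  (`quit_frac`, jittered with SD 0.08) the animal stops at its next lower
  set-point and stays at ambient. This is the mechanism behind the
  treatment effect on time spent thermoregulating: under low thermal cost
  the animal meets its needs early and spends the rest of the test off the
  heat. Standalone default is 1 (never quit); the cohort treatments set it.

The cohort generator (`simulate_cohort()`) runs every animal once per
treatment (repeated measures) and injects treatment effects as: additive
set-point shifts (down with windspeed, defaults 0 / −0.8 / −2.4 °C upper and
0 / −1.3 / −2.2 °C lower, making the passivity range broadest in the middle
treatment); a `k_cool` multiplier (1 / 1.6 / 2.5 — wind strips the boundary
layer); thermoregulation probabilities 17/28, 23/28, 23/28; rest scaling
(1 / 0.5 / 0.2); and quit fractions 0.55 / 0.70 / 0.85. The effect
*directions* mirror the emulated findings; their magnitudes are this
package's stated world, chosen once for realism, not asserted as estimates
of the real effect sizes.

What a green recovery test does establish: the annotator recovers known
set-points within the one-step overshoot bound plus noise, classification
agrees with ground truth, and injected orderings survive the full pipeline.
What it does not establish: anything about real skinks — the generator has
no spatial tunnel gradient, no operative-temperature model, no dehydration
physiology, and its db and bout-count distributions are not calibrated to
the real data (db here tracks time-at-ambient far more strongly than in the
published tests).

## Recovery tolerances

With switching on the latent series, the observed extremum overshoots the
true set-point by at most one Newtonian step plus one quantization step:
`(t_hot - U*)(1 - exp(-k_warm dt)) + resolution` for upper events
(symmetrically `(L* - ta)(1 - exp(-k_cool dt)) + resolution` for lower).
Acceptance adds a `3·noise_sd` allowance for measurement noise; per-trace
recovered set-point means are compared to the realized (jitter-drawn)
ground-truth means the simulator records, since jitter is part of the truth,
and cohort means must land within 0.2 °C. One residual bias is worth
knowing: the detector reports the running *maximum* of the noisy series, so
near a slowly-approached upper set-point the expected maximum of several
noise draws adds roughly +0.1–0.15 °C; it stays well inside the tolerance
but is visible in cohort means.

## The statistical layer

The original analysis used mixed models with animal as a random effect;
re-implementing that machinery is out of scope and the per-trace summary
table (`summaries_to_df()`) is exported precisely so such models can be fit
elsewhere. The self-contained substitute is a seedable permutation test:
overall statistic = variance of group means with all labels permuted;
pairwise contrasts = absolute difference of two group means with labels
permuted *only within those two groups* (joint permutation would let a
strong third group dilute a real contrast); p-values use the add-one
estimator and pairwise p-values are Holm-adjusted. With repeated animals
the default scheme permutes treatment labels within each animal,
respecting the repeated-measures design. Validity is checked directly: the
null rejection rate at α = 0.05 over 1000 null replicates must sit in
0.05 ± 0.02.

## Known limitations

* The source script's behaviour at section boundaries is undocumented; the
  per-bout state reset is this package's convention (flagged for
  sensitivity analysis via `annotator_config`).
* Quantization can shift a detected extremum index a few samples early
  along a plateau (kind sequence and temperatures are unaffected beyond one
  resolution step); exact index equality between quantized and unquantized
  annotation holds only while the latent slope exceeds the resolution per
  step.
* `n_bouts` counts noise flicker around ambient unless smoothing is enabled.
* The simulator's 87–90 min truncation variability is not emulated
  (`duration_s` is exact); any duration ≥ 2 samples is accepted on input.
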