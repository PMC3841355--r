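---
title: "Methods: raw accelerometry processing and trial arithmetic in actitrial"
author: "actitrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raw accelerometry processing and trial arithmetic in actitrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actitrial)
```

# What the package computes

`actitrial` models the computational chain of a waitlist-controlled
randomized trial whose primary outcome is the relative change in objectively
measured daily physical activity: raw tri-axial acceleration is turned into
daily activity counts and MVPA minutes, a two-arm cohort is randomized,
powered and analysed, and a synthetic-data generator supplies ground-truth
inputs for every stage. This vignette documents the models, the parameters
that matter, the numerical choices, and what the tests do and do not
demonstrate.

# The signal model and its processing

## Raw signal

A recording is a matrix of accelerations in g at sampling frequency `fs`
(protocol value 85.7 Hz). At rest the sensor sees the 1 g gravity vector in
some orientation; movement adds an oscillatory component plus wide-band
noise. The generator reproduces exactly this decomposition:

* **gravity**: a unit vector, optionally rotating slowly in a plane with
  period `orientation_drift_period` (default 3600 s in the reduced-scale
  fixtures). Drift emulates posture change during wear; its rate
  (~1/3600 Hz) is far below the filter cutoff, so a correct high-pass
  rejects it. With no noise and no bouts the resultant is *exactly* 1 g at
  every sample — a conservation property the tests assert.
* **bouts**: each activity bout is a sinusoid at `frequency` (default 2 Hz,
  a cadence-like rate well above the 0.27 Hz cutoff) along a random unit
  direction, scaled so that the RMS of its resultant equals the configured
  `amplitude` (g). Counts are linear in amplitude, which is what makes
  ground-truth injection exact: scaling all bout amplitudes by `1 + r`
  (`inject_activity_effect`) scales the bout contribution to the daily
  count by `1 + r`.
* **noise**: i.i.d. Gaussian per axis with SD `noise_sd`. During non-wear
  the gravity vector is frozen and the noise SD divided by 100 — the
  signature of a device lying on a table, which the automated non-wear
  detector keys on.

What the generator does **not** reproduce: device-specific noise spectra,
autocalibration error, temperature drift, or the heavy-tailed, highly
autocorrelated structure of real human movement. Passing end-to-end tests
therefore demonstrates correctness of the *processing arithmetic* under a
controlled signal model, not validity of any particular cut point or
non-wear threshold on real devices.

## High-pass filter

Each axis is filtered independently *before* the resultant is taken, with
the first-order recursive analogue of an analog RC high-pass:

y[t] = alpha * (y[t-1] + x[t] - x[t-1]),  alpha = RC / (RC + 1/fs),
RC = 1 / (2 * pi * fc),  fc = 0.27 Hz.

The filter is causal (forward only); its warm-up transient (10·RC ≈ 5.9 s)
is excluded from the first day's integrals by `process_recording`. The
initial condition `x[0] := x[1]` starts the output at zero, so a constant
input produces an identically zero output.

A numerical point worth recording: this backward-difference discretization
matches the analog magnitude response `(f/fc)/sqrt(1+(f/fc)^2)` only when
`f << fs`. At `fs = 85.7` Hz the deviation at 10 Hz is about 1% — inherent
to the discretization, not a bug. The filter-gain tests therefore measure
the sine response at `fs = 2000` Hz, where discretization error is below
the 10⁻³ tolerance at all three probed frequencies (the cutoff itself,
2 Hz and 10 Hz); the step-response test checks the e⁻¹ decay at `t = RC`
within a discretization tolerance of 2·10⁻³.

## Resultant, counts, epochs

The resultant `R = (x² + y² + z²)^0.5` is rotation invariant, and because
the same linear filter is applied to every axis, the whole pipeline is
invariant under a fixed rotation of the raw signal (tested). Daily activity
counts are rectangle-rule integrals `sum(|R_i|)/fs` over wear samples in
consecutive `day_length` blocks from the recording start — days are not
midnight-aligned because wear starts at an arbitrary daytime visit; the
first partial day is not discarded. Units are g·s; commercial devices print
unitless "counts" on an unknown scale, so only scale-free quantities
(relative changes) are compared anywhere. Epochs are the same integral over
60 s windows; by construction epoch sums over a full-wear day equal the
daily integral (additivity, tested at 10⁻⁶ relative tolerance).

## Non-wear

The trial this package models reviewed non-wear visually; `actitrial`
automates it: a sample is non-wear iff it lies inside a run of at least
`nonwear_window` seconds (default 1800 s) in which the rolling per-axis SD
stays below `nonwear_sd_threshold` (default 0.013 g) on **all three** axes.
Both values are configurable; 30 min/0.013 g is the common actigraphy
heuristic. Self-reported intervals are unioned in via
`merge_reported_nonwear`. Non-wear of any length is excluded from
integrals and never imputed. Boundary behaviour is inherently fuzzy: a
window that straddles a gap edge can be "low" if the wear-side noise is
close to the threshold, smearing the detected gap by up to
`window · (threshold/noise_sd)²` seconds per side; the recovery test uses
0.05 g wear-side movement noise, where the smear is small (Jaccard ≥ 0.9
against the injected gap).

## Intensity classification and valid days

Epoch values are classified with inclusive lower bounds: moderate iff
`moderate ≤ value < vigorous`, vigorous iff `value ≥ vigorous`; MVPA is
their union. Epochs worn < 50% of their length are classified below —
conservative, because a half-empty epoch cannot reach a full-epoch
threshold honestly. The shipped cut points (3 and 10 g·s per 60-s epoch)
are explicitly *synthetic* defaults: the trial cites a published MET
cut-point method without printing numbers, so no literature value is baked
into code, and every test calibrates its synthetic signal against the
configured thresholds rather than the other way round.

A participant is included iff ≥ 5 of the first 7 days are valid, and means
are taken over the first 5 **valid** days. The protocol text ("the first 5
days") does not say what happens when an early day is invalid; averaging
the first five valid days keeps the intended 5-day exposure and is the
choice documented here.

# Design arithmetic

* **Eligibility**: age 60–70 inclusive at both ends (the stated range read
  inclusively), no diabetes/glucose-lowering medication, no disability,
  internet-connected PC, and strictly `< 3` hours/week of exercise and
  cycling combined.
* **Randomization**: within each gender stratum, permuted blocks of 12 —
  each block a uniformly random permutation of 6 intervention + 6 control
  slots. Every complete block is exactly balanced; worst-case overall
  imbalance is `n_strata · block_size/2`. The observed 119/116 split of
  the modelled trial respects that bound.
* **Sample size**: the z-based closed form
  `n/arm = ⌈2 (z₁₋α/₂ + z_power)² σ²/δ²⌉` gives 99/arm (198 total) at
  δ = 10, σ = 25, α = 0.05, power 0.80 — reproducing the trial's printed
  198 exactly, which is why the z form (not an iterative t-based one) is
  the default. Dropout inflation uses `⌈n/(1−rate)⌉` = 233 at 15%; the
  trial printed a target of 232, which matches neither the division nor
  the multiplication convention, so the discrepancy is documented rather
  than reproduced.
* **Empirical power**: vectorised Monte-Carlo simulation of the two-sided
  equal-variance t test (the same statistic as `between_group_test`); at
  n = 99/arm the closed-form normal approximation gives
  `Φ(10/(25·√(2/99)) − 1.96) = 0.8035`, and 20,000 replicates land within
  Monte-Carlo error of it.

# Statistical analysis

Within-group changes use a paired Student t test on the chosen scale: raw
differences, differences of natural logs for right-skewed outcomes
(insulin, HOMA, triglycerides, CRP-like variables — the ln path is
scale invariant, tested), or per-participant relative changes for activity
counts. Between-group comparisons use the equal-variance Student t test
("Student t" being the classical default; Welch is a switch), except
relative MVPA change, which uses the two-sided Wilcoxon rank-sum test —
exact for untied arms under 25, otherwise the normal approximation with
tie correction and no continuity correction (so identical samples give
p = 1). Every p-value path is cross-checked in the tests against an
independently hand-coded statistic + CDF computation at 10⁻⁸, and the
exact rank-sum against full enumeration of assignments for n ≤ 10.

Analysis populations: ITT = all randomized with outcome data (no
imputation, matching the modelled trial's explicit choice); per-protocol
additionally restricts the intervention arm to 12-week program completers,
never touching the control arm. Degenerate inputs (changes constant to
numerical precision) are flagged rather than tested: SE 0, p = 1 when the
change is identically zero, missing otherwise.

Derived endpoints are the standard formulas: BMI `kg/m²`, waist/hip ratio,
HOMA-IR `glucose·insulin/22.5` (mmol/L, mU/L), Friedewald
`LDL = TC − HDL − TG/2.2` valid only at TG ≤ 4.52 mmol/L (400 mg/dL).
Note that published cohort tables report means/medians of per-person
derived values; applying a formula to marginal summary statistics does not
reproduce those entries and is not expected to.

# The cohort generator

`default_cohort_spec()` encodes the study conditions of the modelled trial:
119/116 randomized, observed dropout 9/235, program completion 104/114
among intervention completers, 41% female. Changes are drawn normal on the
reported scale with SD = SE·√n at the analyzed arm sizes (e.g. ankle
counts: +46%, SD = 0.07·√107 vs +12%, SD = 0.03·√109; weight −1.49 kg,
SD = 0.26·√114 vs −0.82 kg, SD = 0.21·√112). The trial reports only means
and SEs of changes, so the distributional shape is a modelling choice:
normal on the stated scale, documented here. Baselines of relative-scale
outcomes (activity counts) are positive quantities, so the normal tail
below zero is resampled; right-skewed baselines (MVPA minutes) are
log-normal matched to the reported median/IQR scale.

# Problem sizes and reproducibility

All stochastic functions take explicit integer seeds and restore the
caller's RNG state. The test suite runs the signal pipeline in
reduced-scale mode — 10 Hz sampling, 2-hour "days", 7-day windows — which
is an exact configuration of the same code path (every window is defined
in seconds), chosen so the full suite completes in under a minute; power
and calibration simulations use 10,000–20,000 replicates, and the
randomization fairness check 4,000–10,000 seeds. The acceptance script
uses 20,000 replicate trials at the design sample size.

# Known limitations

* Cut points, and hence absolute MVPA minutes, are synthetic calibrations;
  only within-pipeline comparisons are meaningful.
* The count unit (g·s) is not the unitless device count scale; only
  relative changes are comparable across the two.
* The non-wear detector is a heuristic stand-in for human review; its
  boundary smear depends on the wear-side noise level.
* The generator's normal change model cannot exhibit the skewness that
  motivated the trial's rank-sum test for MVPA; the rank-sum path is
  validated against enumeration, not against a realistic skewed cohort.
* Framingham risk scoring, body-composition device internals and the
  coaching program itself are out of scope.
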