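# actitrial

Tools for the full computational chain of a waitlist-controlled randomized
trial of a physical-activity intervention in inactive 60–70-year-olds, where
the primary outcome is the *relative change in daily activity counts*
measured by raw tri-axial accelerometers worn 24 h/day at wrist and ankle.

The package covers three layers that usually live in separate scripts:

1. **Raw-signal processing** — each axis of a recording (g units, default
   85.7 Hz) is passed through a first-order RC high-pass filter
   (f<sub>c</sub> = 0.27 Hz) to remove the static gravity component, the
   resultant `R = (x² + y² + z²)^0.5` is integrated over wear time into
   daily *activity counts* (g·s) and 1-minute epochs, epochs are classified
   against MET-style cut points into moderate/vigorous intensity (MVPA
   minutes/day), non-wear is detected automatically (rolling per-axis SD
   below 0.013 g for ≥ 30 min on all axes) and excluded, never imputed, and
   participants enter the analysis only with ≥ 5 valid days out of 7
   (averages over the first 5 valid days).
2. **Trial design arithmetic** — eligibility screening (age 60–70, no
   diabetes, no disability, internet access, < 3 h exercise+cycling per
   week), gender-stratified 1:1 permuted-block randomization (block size
   12), the normal-approximation two-sample sample size
   `n/arm = ⌈2 (z₁₋α/₂ + z_power)² σ² / δ²⌉` with dropout inflation, and a
   Monte-Carlo check of the achieved power.
3. **Outcome analysis** — paired t tests within arms (ln-transformed for
   skewed outcomes), equal-variance unpaired t tests (rank-sum for skewed
   MVPA changes) between arms, intention-to-treat vs per-protocol
   populations, and derived metabolic endpoints (BMI, waist/hip ratio,
   HOMA-IR `= glucose·insulin/22.5`, Friedewald LDL `= TC − HDL − TG/2.2`).

Because raw participant recordings of such trials are rarely deposited, the
package ships a first-class **synthetic-data generator**: raw recordings
with a 1 g gravity vector under slow orientation drift, sinusoidal activity
bouts of configurable amplitude/duration, sensor noise and non-wear gaps;
and two-arm cohorts with configurable per-arm change distributions. Every
downstream stage is tested against this known ground truth.

## Worked example

```r
library(actitrial)

# design arithmetic: delta = 10 percentage points, SD = 25, power 0.80
d <- sample_size_two_means(design_spec())
d$n_per_arm                                  # 99
d$n_total                                    # 198
inflate_for_dropout(d$n_total, 0.15)         # 233
empirical_power(design_spec(), 99, 20000, seed = 1)   # 0.8002

# simulate a cohort at the default study conditions and analyse it
co <- simulate_cohort(default_cohort_spec(seed = 42))
et <- build_effect_table(itt_subset(co), default_analysis_plan())
et[, c("outcome", "mean_change_int", "se_int",
       "mean_change_ctl", "se_ctl", "p_between")]
#>        outcome mean_change_int se_int mean_change_ctl se_ctl p_between
#> 1 ankle_counts           0.464 0.0630          0.1804 0.0346  0.000103
#> 2 wrist_counts           0.146 0.0319          0.0578 0.0192  0.018967
#> 3     mvpa_min           0.795 0.2231          0.2811 0.1877  0.065570
#> 4    weight_kg          -1.347 0.2504         -0.4809 0.2135  0.009090
```

The ankle row reads: the simulated intervention arm increased daily
activity counts by 46.4% (SE 6.3%) versus 18.0% (SE 3.5%) in the waitlist
controls, with a between-arm equal-variance t-test p of 1e-4; weight changed
by −1.35 kg vs −0.48 kg. One seed gives one realization — the generator's
configured means are 0.46/0.12 and −1.49/−0.82.

Raw-signal processing runs the same way at full or reduced scale:

```r
prof <- activity_profile(
  bouts = data.frame(start = 1200, duration = 600, amplitude = 0.5,
                     frequency = 2),
  noise_sd = 0.005, wear_days = 7, day_length = 7200,
  orientation_drift_period = 3600)
rec  <- simulate_recording(prof, fs = 10, seed = 1)
cfg  <- pipeline_config(fs = 10, day_length = 7200, nonwear_window = 600)
process_recording(rec, cfg)$summary
```

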