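# circdip

Circadian heart-rate profiling and nocturnal dipping analysis for stroke
outcome prediction.

## What it does

Patients on a stroke unit are continuously monitored; the monitor's beat
annotations (timestamps, beat-to-beat RR intervals, beat labels) carry
information about autonomic function that routine vitals miss. `circdip`
turns those annotations into circadian profiles of heart rate (HR) and
heart rate variability (HRV) and asks whether the physiological *nocturnal
dip* of HR — its night-time fall relative to daytime — separates patients
who leave the hospital functionally independent (modified Rankin Scale,
mRS 0–2) from those with an unfavorable outcome (mRS 3–6).

The pipeline:

1. **Ingest & filter** — read beat-annotation CSVs, keep the first 48 h
   after admission, retain only normal (sinus) beats, and apply the
   exclusion cascade (too few normal beats → missing covariates → known
   atrial fibrillation), with a flow report whose counts always sum.
2. **Segment metrics** — per wall-clock 5-min segment: HR (median of
   60000/RR), SDNN, RMSSD, and LF (0.04–0.15 Hz) / HF (0.15–0.4 Hz)
   spectral power of the spline-resampled RR tachogram (4 Hz, periodogram,
   band integration in ms²).
3. **Circadian profiles** — hour-of-day medians over segments, an hourly
   value requiring at least 3 of the possible 24 segments per clock hour.
4. **Dipping statistic** — per patient,

   `percent_decline = 100 × (HR_day − HR_night) / HR_day`

   with night = 22:00–05:00 and day = 10:00–17:00; group summaries are
   mean ± SEM, and per-hour group differences use Mann–Whitney U tests
   with a fixed ×24 Bonferroni correction.
5. **Matching** — propensity-score matching of outcome groups on age and
   NIHSS (logistic propensity, greedy 1:1 nearest neighbour on the logit
   scale, no replacement, caliper 0.2 SD of the logit propensity).
6. **Outcome models** — nested stratified 5×5-fold cross-validation
   (repeated shuffles) of ridge logistic regression and gradient-boosted
   trees predicting the dichotomized outcome from clinical features, with
   and without the nocturnal HR feature; unit-norm feature importances
   (standardized coefficients / TreeSHAP attributions) and a two-sample t
   test over shuffles compare the two feature sets.

Because real stroke-unit data cannot be shipped, the package includes a
first-class **synthetic cohort generator**: RR series with a smooth
circadian dip, in-band LF/HF oscillations, Gaussian RR noise, ectopic
beats with compensatory pauses, recording gaps, AF-like irregular series,
paced recordings, imbalanced covariates, and a logistic outcome link —
everything downstream is testable end to end.

## Worked example

```r
library(circdip)

spec   <- cohort_spec(n_good = 30, n_unfavorable = 30,
                      duration_hours = 24, seed = 42)
cohort <- generate_cohort(spec)
excl   <- apply_exclusions(cohort, window_hours = 24)
excl$flow
#>   initial excluded_insufficient_beats excluded_missing_fields excluded_af
#> 1      60                           0                       0           0
#>   excluded_paced analyzable
#> 1              0         60

segments <- compute_segment_metrics(excl$cohort$beats, metrics = "hr")
profiles <- cohort_profiles(segments, "hr")
groups   <- data.frame(
  patient_id = excl$cohort$covariates$patient_id,
  group = dichotomize_outcome(excl$cohort$covariates$mrs_discharge))

group_dip_summary(cohort_dips(profiles), groups)
#>         group mean_percent_decline       sem  n
#> 1        good             9.550657 0.5509268 25
#> 2 unfavorable             6.971509 0.3576949 35
```

Patients with a good outcome show a ~9.6 ± 0.6 % nocturnal HR decline
versus ~7.0 ± 0.4 % for unfavorable outcome: the generator's link between
blunted dipping and worse outcome is recovered from the beat level. (At 60
patients the per-hour Bonferroni-corrected tests are deliberately
conservative and typically flag nothing; hourly significance emerges at
larger cohort sizes.) `run_pipeline(pipeline_config(...))` chains all the
stages, including matching and the nested-CV models, and writes every
artifact plus a manifest to a run directory.

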