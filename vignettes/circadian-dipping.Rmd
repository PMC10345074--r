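---
title: "Circadian HR profiling and nocturnal dipping: models and methods"
author: "circdip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian HR profiling and nocturnal dipping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circdip)
```

## The scientific question

Heart rate normally falls during the night. A blunted nocturnal dip
("non-dipping") reflects autonomic dysregulation and has been linked to
worse cardiovascular and cerebrovascular outcomes. On a stroke unit,
continuous ECG monitoring yields beat-to-beat (RR) interval annotations
for every patient; `circdip` quantifies each patient's circadian HR/HRV
profile from those annotations and relates the nocturnal HR dip to
dichotomized functional outcome at discharge (mRS 0–2, independent, vs
mRS 3–6, dependent or dead).

## From beats to circadian profiles

**Filtering.** Only beats annotated as normal sinus beats enter the
analysis; paced and ectopic beats are dropped. Analysis is restricted to
the half-open 48 h window after admission. Patients are excluded, in a
fixed first-failure order, for (1) insufficient normal beats, (2) missing
required covariates, (3) a known AF diagnosis, (4) majority-paced
recordings. AF invalidates standard HRV comparison (the rhythm is
irregularly irregular), which is why it is an exclusion rather than a
covariate; a switch disables the AF rule for robustness analyses. The
threshold behind "insufficient" is site-specific and is therefore a
configurable parameter (`min_normal_beats`, default 5000 over 48 h —
roughly a 10 % duty cycle at 60 bpm, enough to populate several hourly
slots).

**Segment metrics.** The series is cut on the wall-clock 5-minute grid
(hh:00, hh:05, …, half-open). The grid is clock-aligned, not
admission-aligned, because hour-of-day profiling is clock-relative. Per
segment with at least 30 beats:

* HR = median over beats of 60000/RR (bpm); medians use the midpoint
  convention for even counts.
* SDNN = population standard deviation of RR (ms).
* RMSSD = root mean square of successive RR differences (ms), computed
  only over *valid* pairs: a pair whose time gap exceeds twice the
  segment's median RR straddles a removed beat or a recording gap and is
  skipped, because such pairs produce artifactual RMSSD spikes. Stored RR
  values are never re-derived from timestamps.
* LF and HF power: the tachogram (beat time vs RR) is interpolated with a
  cubic spline (near-interpolating by default; a smoothing parameter is
  exposed), resampled on a uniform 4 Hz grid, mean-removed, and its
  one-sided periodogram PSD (ms²/Hz) integrated by the rectangle rule
  over 0.04–0.15 Hz (LF) and 0.15–0.4 Hz (HF). Resampling "by a factor
  of 4" is interpreted as 4 samples per second — the standard HRV choice,
  giving a 2 Hz Nyquist frequency far above the 0.4 Hz band edge; the
  rate is configurable since other readings (4× mean HR, 4× upsampling)
  exist. Segments must span at least 150 s to resolve the 0.04 Hz band
  edge (6 cycles of the slowest LF component) and have at least 16 beats.
  The PSD normalization is chosen so that the band powers integrate to
  ms² and their sum over all frequencies equals the grid variance
  (Parseval), which the tests verify against single-tone inputs of known
  amplitude (a tone of amplitude A carries A²/2 of power).

**Hourly profiles.** Segment values are pooled by clock hour across both
recording days (up to 24 segments per hour). The hourly value is the
median over contributing segments — consistent with the robust per-segment
medians — and a slot is emitted only when at least 3 segments contribute.

## The dipping statistic

Per patient, with night hours {22, 23, 0, 1, 2, 3, 4} (22:00–05:00) and
day hours {10, …, 16} (10:00–17:00):

$$\text{percent decline} = 100 \cdot \frac{\overline{HR}_{day} - \overline{HR}_{night}}{\overline{HR}_{day}}$$

Window means weight available hourly slots equally (the hourly value is
the unit of analysis, not the segment), and the statistic is computed per
patient and then summarized per group as mean ± SEM — computing per
patient is what makes a standard error meaningful. Negative values are
preserved (reverse dippers). No dipper/non-dipper dichotomy is imposed:
the dip is analyzed as a continuous quantity.

Per-hour group comparisons use two-sided Mann–Whitney U tests on
patient-level hourly values with a Bonferroni factor fixed at 24
regardless of how many hours were testable — conservative by design, and
it keeps the corrected p-values comparable across analyses with different
missingness. The same night-window mean HR (22:00–05:00) is exported as
the *nocturnal HR* feature for outcome modelling.

## Matching

Outcome groups are imbalanced in age and stroke severity, and HR/HRV are
strongly age- and severity-dependent. Propensity-score matching on age
and NIHSS (logistic propensity of being in the unfavorable group) uses
greedy 1:1 nearest-neighbour matching on the logit propensity, without
replacement, iterating the minority group in seeded random order. The
caliper 0.2 is interpreted on the conventional scale — 0.2 SD of the
logit propensity (Austin's rule) — with a raw-probability option, since
the bare number "0.2" is library-dependent. Under separation the
propensity model falls back to a lightly ridge-penalized fit
(penalty 1e-4) so small simulated cohorts remain runnable. Balance is
reported as standardized mean differences before/after matching; an
age-only preset and a no-matching preset support robustness analyses.

## Outcome models

Features: age, sex (0/1), NIHSS, hypertension, diabetes, prior myocardial
infarction, coronary artery disease, pneumonia, ordinal troponin category,
GFR, and optionally nocturnal HR. Serial troponin is coded 0 (all samples
< 14 ng/l), 1 (any sample above 14 ng/l), 2 (an elevated sample plus a
second sample differing from it by ≥ 20 %); an empty sample list is
missing data, not category 0.

Evaluation is nested cross-validation: per shuffle, a stratified outer
5-fold (4:1) split; per outer fold, features are standardized with
training-fold statistics only (fitting the scaler globally would leak
test information into tuning), an inner stratified 5-fold grid search
maximizes inner AUC, and the winner is refit and scored on the held-out
fold. Both fold levels re-randomize across shuffles. Ties in the grid
search resolve to the less complex candidate (stronger regularization,
smaller depth) for determinism.

Two families are implemented. Ridge logistic regression tunes the inverse
regularization strength over a 50-point grid spanning 0.1–1000; the
strength C maps to the glmnet ridge penalty as λ = 1/(nC) (the two
objectives differ by a 1/n scaling). Gradient boosting uses xgboost with
depth {2, 4, 6}, 20 learning rates in [0.03, 0.3], row subsampling
{0.6, 0.8, 1} and L2 leaf regularization {3, 10, 100, 500}; the number of
boosting rounds is fixed (default 50) rather than tuned.

Feature importance is the absolute standardized coefficient vector
(logistic) or the mean absolute per-sample TreeSHAP attribution per
feature (boosting), each scaled to unit Euclidean norm so rankings are
comparable across model families; an all-zero vector is returned
unnormalized with a flag. Configurations with and without nocturnal HR
are compared by a standard two-sample location t test on the per-shuffle
mean AUCs; identical inputs are defined to give t = 0, p = 1. Inner
tuning maximizes AUC (the reported performance metric) rather than
accuracy.

## The synthetic cohort generator

The generator produces what the analysis assumes about stroke-unit data:

* **Circadian HR**: instantaneous target rate
  $h(t) = HR_{day}\,(1 - d\,w(t))$ with dip fraction $d$ and a night
  weight $w(t)$ that is 1 on the nocturnal plateau and ramps with a
  raised-cosine over `transition_minutes` (default 60) *centred* on the
  window edges. The cosine ramp avoids discontinuities that would leak
  broadband power into the LF/HF bands; centring the ramp on the stated
  boundary keeps hourly medians unbiased with respect to the nominal
  day/night levels.
* **RR model**: each interval is 60000/h(t) plus an LF-band and an
  HF-band sinusoid (amplitudes in ms) plus Gaussian noise, floored at
  300 ms and capped at 2000 ms for physiological plausibility. Beat times
  are the cumulative sum of intervals; the mutual dependence of times and
  intervals is resolved by a vectorized fixed-point iteration (4 sweeps),
  which converges to well below 1e-6 relative error because the
  modulations are slow and small relative to the beat period.
* **Artifacts**: a seeded fraction of beats is relabelled ectopic with the
  classic premature-beat shape (annotated RR 0.6×, following beat 1.4× as
  compensatory pause) — exercising the normal-beats-only rule; recording
  gaps delete beats in given windows; paced patients carry majority
  paced-labelled beats; AF-like patients get RR = exp(Gaussian AR(1))
  rescaled to a mean of 800 ms — irregularly irregular, without circadian
  structure — plus the AF diagnosis flag.
* **Cohort**: covariates are drawn per group with defaults loosely
  calibrated to an elderly stroke population (mean age ≈ 72 vs 77 years,
  NIHSS ≈ Poisson(5)/Poisson(6), hypertension 74 %/91 %, GFR ≈ 74
  ml/min); the per-patient dip fraction is a mean-corrected lognormal
  jitter of the group value (multiplicative, so a group dip of 0 stays
  exactly 0 and the group mean is preserved); day HR defaults are 76/78
  bpm with dips 0.105/0.063, and LF/HF amplitudes (37/45 ms) and RR noise
  (24 ms) chosen so typical segment SDNN ≈ 48 ms and band powers fall in
  the several-hundred-ms² range. Discharge mRS is drawn so that
  P(mRS > 2) follows a logistic link on centred and scaled age, NIHSS,
  dip fraction, generative nocturnal HR and comorbidity count. The
  default coefficients (0.5, 0.8, −1.2, 1.0, 0.2, intercept 0) encode the
  association the package is built to detect — non-dipping and higher
  nocturnal HR increase the odds of unfavorable outcome on top of age and
  severity — strongly enough to be recoverable at a few hundred patients.

**What it does not emulate**: real RR noise is not an additive pair of
sinusoids (no respiratory coupling, no 1/f background, no movement
artifacts); troponin values are group-shifted lognormals rather than
infarct dynamics; admission times are uniform over the day. Passing tests
therefore demonstrate the *pipeline's* correctness and statistical
calibration under a controlled generative model, not clinical validity on
real recordings.

## Numerical and degenerate-input conventions

* Half-open intervals everywhere (window trim, segment bins, frequency
  bands); a beat exactly at the 48 h boundary is excluded (with a 1 µs
  guard against floating-point leakage of an exactly-boundary beat).
* A zero-variance segment has LF = HF = 0 by definition (no spectral
  machinery is invoked); below-quorum segments/slots are missing (`NA`),
  never zero.
* LF/HF is missing when HF = 0; an empty troponin list is missing, not
  category 0; an mRS outside 0–6 is a validation error.
* Matching with identical propensities everywhere treats the caliper as
  infinite (the SD of the logit propensity is 0); zero surviving pairs is
  a valid empty result, not an exception.
* All timestamps are handled as time-zone-naive local clock times
  (internally UTC), since circadian analysis is clock-relative.
* Every stochastic stage takes an explicit seed and is byte-reproducible;
  child seeds are derived from the master seed.

## Problem sizes in the shipped tests

The test-suite simulations are sized to run in a couple of minutes while
keeping the stated tolerances: dip-parameter recovery uses 40
patients/group × 3 seeds × 24 h recordings at generator dips
{0, 0.05, 0.10} (tolerance 1 percentage point); hourly-test calibration
uses 200 profile-level null cohorts (family-wise error ≤ 0.10); matching
balance uses 100 seeded cohorts of 400/group (post-match SMD < 0.1 in
≥ 95 % of runs); ML checks use 300-patient feature tables with 10
shuffles. `scripts/acceptance.R` runs the full beat-level pipeline on a
60/80-patient, 24 h cohort plus a 40-patient dip-recovery cohort.

## Known limitations

* The greedy matcher is order-dependent (seeded); optimal matching is out
  of scope.
* The spectral estimator is a plain periodogram on spline-resampled data;
  Welch averaging or Lomb–Scargle on irregular samples would be natural
  extensions.
* Per-hour Mann–Whitney tests with a fixed ×24 Bonferroni factor are
  conservative; at small cohort sizes no hour may reach significance even
  under a real group difference.
* Nonlinear/fractal HRV measures are not implemented.
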