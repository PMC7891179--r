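---
title: "Oculomotor biomarkers: models, parameters and design choices"
author: "oculomark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oculomotor biomarkers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculomark)
```

## The scientific problem

Eye movements are controlled by a widespread cortical network, and
neurodegenerative diseases damage that network in disease-specific spatial
patterns. Alzheimer's disease, with predominantly posterior (parietal and
posterior temporal) pathology, degrades visually-guided behaviour — pursuit
accuracy and prosaccade latency; behavioural-variant frontotemporal dementia
(bvFTD), with frontal pathology, degrades the volitional tasks — antisaccades
and memory-guided saccades; semantic-variant primary progressive aphasia
(svPPA) spares most oculomotor behaviour. A standardized video-oculography
battery — prosaccade, antisaccade, memory-saccade and sinusoidal smooth
pursuit tests — therefore yields a parameter profile with diagnostic
information, and a machine-learning classifier over those parameters can
support the differential diagnosis.

`oculomark` implements that analysis chain end to end: a generative model of
raw gaze recordings calibrated to published group-level parameter tables, an
event-detection and parameter-extraction stage, the univariate group
statistics, and the classification stage with its cross-validated confidence
loop.

## The oculomotor battery and its parameters

Each saccadic test has 12 horizontal trials (targets at ±5, ±10, ±20 deg)
followed by 8 vertical trials (±5, ±12 deg); the pursuit test has 6 + 6
trials of a sinusoidally moving target. Parameters fall in three domains:

* **Accuracy** — signed endpoint error, `|final gaze eccentricity| −
  |reference eccentricity|`: overshoot (hypermetria) positive, undershoot
  (hypometria) negative; positive and negative errors are averaged
  separately. Pursuit error is the mean absolute eye−target position
  difference over valid, non-saccadic samples (an RMS option exists).
* **Time** — latency from the go event (target onset; blank onset for
  memory trials) to saccade onset; pursuit gain, the ratio of eye to target
  velocity.
* **Success** — % correct antisaccades, % corrected antisaccades
  (corrections / erroneous trials), % successful antisaccades (correct +
  corrected, over attempts), % correct memory saccades. Success parameters
  are pooled over planes; time and accuracy parameters are kept per plane.

## Event detection

Saccades are detected on a Savitzky–Golay smoothed derivative (quadratic
fit, ~50 ms centered window) with a 30 deg/s velocity threshold, 1 deg
minimum amplitude and 10 ms minimum duration, all configurable
(`default_detection_params()`). Because threshold crossings on a smoothed
derivative are biased estimates of movement onset, boundaries are refined
from the position trace: for a symmetric displacement profile the crossing
of the halfway position marks the temporal centre of the movement and is
invariant under symmetric smoothing; onset and offset are placed half a
main-sequence duration (`20 ms + 2 ms/deg × amplitude`) either side of that
centre. This estimator is unbiased to well under one sample on the
package's kinematic model, which the detection tests verify against a
brute-force finite-difference oracle.

Two further conventions matter:

* **Pursuit excision.** At the default ±20 deg / 0.25 Hz sinusoid the
  *target* peaks at ~31 deg/s, above the saccade threshold, so intrusions
  are detected on the eye-minus-target residual with a dedicated 60 deg/s
  threshold — far above residual pursuit velocity and velocity noise, far
  below genuine catch-up saccades.
* **Blink censoring.** A blink after the primary antisaccade response could
  hide a corrective saccade. Trials with post-response (or go-to-response)
  invalid spans are censored from the outcome percentages *uniformly* —
  whatever was observed — because censoring only uncorrected-looking trials
  would inflate the corrected fraction. Latency and error measurements from
  such trials are retained. A memory trial with no detected response counts
  as incorrect unless blinks obliterated the response window, in which case
  it is invalid.

## The synthetic-data generator

No raw recordings are distributed with the published tables, so the
generator is the package's test bed: group profiles (mean, SD of every
parameter; success probabilities; demographics) act as the generative
model. Subject-level latent parameters are drawn from truncated normals
(latencies ≥ 80 ms and capped to their response window, percentages in
[0, 100], gains in [0, 1.5], errors keeping their sign); trial-level values
are then drawn around the subject latents, with endpoint errors clipped to
the trial's eccentricity so that a commanded landing stays detectable and
on the instructed side. Saccades follow a raised-cosine main-sequence
profile; traces carry white positional noise (SD 0.3 deg) and Poisson
blink spans (0.1/s), both configurable.

Pursuit trials are synthesized as `gain × target + offset(t) + noise`,
where `offset(t)` is a random-sign piecewise-constant level with
saccade-like 30 ms transitions (the catch-up-like intrusions); the level is
solved per trial by root finding so that the realized noise-free mean
absolute error equals the subject's truth value. A drawn (gain, error)
pair can be jointly infeasible — the minimum achievable error is
`(2/π)·|1−gain|·A` — in which case the floor is synthesized and recorded.

**The truth is what was actually synthesized.** `SubjectTruth` records the
post-truncation, post-feasibility values per trial, and
`truth_features()` aggregates them with the same rules as the extraction
stage. Parameter recovery is therefore judged against the realized
generating means; in addition, for every parameter whose truncation bounds
lie ≥ 3 SD from the published mean (where truncation cannot shift the
distribution), recovery is judged directly against the published value.
Phase timing (1,000 ms fixation; 1,500 ms targets; a 3,500 ms antisaccade
target phase so late corrections stay in-trial; a 3,000 ms memory response
window; 0.25 Hz pursuit over two cycles) and the 100 Hz sampling rate are
declared package defaults — the published protocol does not state them.

**Known idealization.** Only marginal means and SDs are published, so
features are drawn independently per subject. Real oculomotor parameters
are correlated; independence tends to *overstate* multivariate
separability. Passing classifier benchmarks on synthetic cohorts therefore
demonstrates the pipeline's correctness and its behaviour under the
published marginals, not clinical performance.

## Group statistics

Four-group comparisons use one-way ANOVA with Tukey HSD pairwise contrasts
(the "crude" p-values); covariate adjustment uses linear models with age
and sex, with pairwise covariate-adjusted p-values from model-based
contrasts of estimated marginal means without multiplicity adjustment —
the reported tables' "adjusted P" is read as covariate adjustment, a
documented choice rather than an assertion about the original analysis.
Sedative intake (antidepressants, benzodiazepines, neuroleptics,
antiepileptics) enters as a covariate only when its Spearman correlation
with the parameter is significant below 0.1 (`sedative_screen()`); under
independence this screen admits the covariate at its nominal ~10% rate,
which the tests verify by simulation. Correlation panels against
neuropsychological scores report Spearman's ρ with an age-adjusted p from
a rank-scale linear model.

## The classification stage

The pipeline mirrors the published flow:

1. **Normalization** `x̂ = (x − x̄)/σ`, with the training mean and SD stored
   and re-applied verbatim to held-out or external subjects.
2. **Univariate selection**: features with a pooled-t pairwise p below
   0.001; features that can be missing for an impaired subject
   (corrected-antisaccade latency, memory latency and memory errors) are
   excluded up front, and any remaining feature with a missing value is
   dropped at training time.
3. **Fisher discriminant ratio** ranking, `(μ₁−μ₂)²/(σ₁²+σ₂²)`. The summed
   denominator is the canonical definition; a difference of variances
   (which can be negative) appears in the source material's display and is
   treated as a typographical slip.
4. **Classifier**: linear/RBF SVM (unit cost) or k-nearest neighbours
   (k ∈ {1,3,5,7}), selected by cross-validated AUC (`search_models()`),
   ties broken toward the simpler model.
5. **Confidence loop**: 1,000 iterations of re-randomized stratified 80/20
   splits (each test set mirrors one fold of a five-fold partition);
   best/worst/mean AUC and accuracy over the loop.
6. **External application**: no refitting; stored normalization moments and
   the trained model are applied to an independent cohort.

NIPALS PLS2 (`pls2_fit()`) implements the paired-block decomposition
`X = TPᵀ + E`, `Y = UQᵀ + F` by iterative deflation and is available as an
optional projection stage between selection and classification; the default
pipeline is filter → FDR ranking → classifier, each stage toggleable, since
the ordering of dimensionality reduction and selection is ambiguous in the
source description and both readings are runnable.

**Selection placement.** By default the univariate filter runs inside every
training split (leakage-guarded). A "publication-style" mode selects once
on the full sample before the loop — the flow the original description
implies — and is what the acceptance benchmarks use. Inside the loop an
empty selection falls back to the single top-FDR feature: a confidence
loop that aborts on an unlucky fold cannot report its statistics. The
standalone `select_training_features()` keeps the strict contract and
errors with advice to relax the threshold.

**Permutation-null caveat.** Any *single* label-permuted data set retains a
chance-level empirical association that repeated CV splits all see, so the
null calibration averages the loop's mean AUC over fresh permutations; that
average sits at 0.5.

## Numerical choices and degenerate inputs

* Truncated normals are sampled by inverse-CDF with closed-form moments
  (`rtnorm()`, `tnorm_mean()`, `tnorm_sd()`); a zero SD is a point mass
  (one group corrects 100% of errors with SD 0).
* Pursuit gain is a median of velocity ratios over samples where the
  target moves faster than 20% of its peak; both velocities pass through
  the identical derivative filter, so the filter's attenuation cancels.
* Samples inside half a smoothing window of the trace edges are excluded
  from pursuit statistics (the replicated-boundary fit is biased there).
* Empty denominators (no erroneous antisaccades to correct, no trials of a
  sign) propagate as missing values, never as zeros.
* AUC is the Mann–Whitney rank statistic with ties counted half; degenerate
  single-class folds are resampled.
* All stochastic stages are driven by a single seed; cohorts, feature
  tables and CV reports are bit-reproducible under it.

## Problem sizes used by the checks

The packaged checks simulate 200 subjects per diagnostic group for
parameter recovery (every extracted group mean within 3 SE of its
generating mean), use the published group sizes (29/18/18/7) for the
statistics demonstrations, and evaluate the classifier benchmarks on
marginally-sampled cohorts at the published sizes with the full
1,000-iteration loop. These sizes give recovery tolerances of a fraction
of each parameter's between-subject SD while keeping a complete run in the
minutes range on one CPU.

## Known limitations

* Marginal independence of generated features (see above) — between-feature
  covariance is not published and not modelled.
* The kinematic model is deliberately minimal: no oculomotor-plant
  dynamics, no microsaccades, no pupil analytics; good enough to exercise
  detection, not to study saccade physiology.
* Published group SDs for some parameters are large relative to their
  physiological range (e.g. pursuit gain 0.89 ± 0.78), so truncation
  reshapes those generating distributions noticeably; recovery is judged
  against realized truth for exactly this reason.
* The corrected-antisaccade latency is referenced to the go event by
  default; the alternative reading (time from the erroneous saccade's
  offset) is available via `corrected_latency_ref = "error_offset"`.
* The 50%-of-eccentricity landing rule for a correct memory saccade is a
  declared convention; the source defines correctness only qualitatively.
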