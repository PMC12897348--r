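---
title: "Methods: wakefulness-based OSA severity screening with conformal uncertainty"
author: "osascreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wakefulness-based OSA severity screening with conformal uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Obstructive sleep apnea (OSA) is conventionally diagnosed by overnight
polysomnography, which is slow and resource-intensive. A fast screening
alternative records tracheal breathing sounds (TBS) over the suprasternal
notch while the subject is *awake*, breathing deeply five times through the
nose and five times through the mouth, and combines acoustic features of
those recordings with five anthropometric variables (age, sex, BMI, neck
circumference, Mallampati score) to predict the apnea–hypopnea index (AHI)
severity class:

* non-OSA: AHI < 5 events/h
* mild: 5 ≤ AHI < 15
* moderate: 15 ≤ AHI < 30
* severe: AHI ≥ 30

`osascreen` implements the full analysis chain as a tested R package:
synthetic cohort generation, signal preparation, feature extraction, table
preparation and selection, six one-vs-one bagged base classifiers, a stacked
meta-model for a three-class (moderate and severe merged) and a four-class
scheme, and split conformal prediction sets with a finite-sample coverage
guarantee. Clinical audio is not distributable, so the package ships a
generator whose cohorts emulate the reference population's class sizes
(74/35/50/40) and per-class anthropometric distributions, and every stage is
exercised end-to-end on generated data.

# The synthetic cohort generator

`generateCohort(cohortSpec())` draws, per class:

* **AHI** from a log-normal moment-matched to the class mean ± SD and
  truncated to the class interval (severe capped at 150 events/h). Severity
  is then *derived* from AHI, so the AHI/severity invariant holds by
  construction.
* **Age, BMI, NC** from truncated normals at physiologic bounds (age 18–90,
  BMI 15–60 kg/m², NC 25–60 cm). The underlying mean is solved (by
  `uniroot`) so the *post-truncation* mean equals the population target;
  plain truncation would bias, e.g., non-OSA age by about +0.4 years and
  break distributional checks against the targets.
* **Sex and Mallampati score** from per-class category probabilities. The
  mild-class Mallampati counts in the reference table total 34 of 35
  subjects; probabilities are normalized by the category total.

Each subject owns an RNG stream derived from `(seed, class, index)`, so
cohorts are reproducible and stable under class-size edits.

**Audio.** A recording is `cycles` (default 5) breath cycles at `rate`
(default 16 kHz): 1.2 s inspiration, 0.3 s post-inspiratory gap, 1.6 s
expiration, 0.4 s pause. Each burst is pink-ish noise (one-pole low-pass
shaped white noise) passed through two resonators whose center frequencies
(about 420 and 1150 Hz for non-OSA) and spectral tilt shift linearly with
the severity index scaled by `acousticEffectSize`; the mouth route shifts
the resonances slightly upward, and low-level white sensor noise is added.
With `acousticEffectSize = 0` all classes are acoustically identical in
distribution, which pins downstream classifiers at chance — a property the
tests verify. What the generator does *not* emulate: real airway acoustics,
device/room noise profiles, within-subject session variability, or any
correlation between anthropometrics and acoustics beyond the shared class
label. Passing tests on synthetic cohorts therefore validate the
*machinery* (leakage control, calibration, guarantees, structural
constants), not clinical accuracy.

A second, feature-level generator (`simulateFeatureCohort()`) draws the
anthropometrics identically but produces Gaussian "acoustic" features whose
means shift with severity, skipping audio synthesis. It exists for large
Monte Carlo studies — notably the conformal coverage study, where 500
independent cohorts must be trained per run and only the exchangeability
and class structure of the rows matter, not acoustic realism.

# Signal preparation

Recordings are denoised by spectral subtraction (noise spectrum from the
quietest 10% of frames; skipped when the frame-energy SNR exceeds 25 dB),
then band-passed 75–3000 Hz with a 4th-order Butterworth applied
forward–backward. Zero-phase filtering was chosen so breath onsets are not
delayed; the closed-form forward–backward magnitude is used as the test
oracle. Breath phases are segmented by thresholded windowed log-variance
(window 50 ms, 50% overlap, threshold 25% of the log-variance range,
minimum phase 200 ms), with gaps shorter than the minimum merged and
surviving regions labeled alternately inspiration/expiration starting with
inspiration, matching the deep-breathing protocol. These parameters are
configuration, not constants: the upstream literature does not publish
them, and they were fixed once against the generator's burst structure.

# The feature dictionary

Features are extracted per phase and mean-aggregated per subject separately
for each route × phase combination (prefixes `nose_insp_`, `nose_exp_`,
`mouth_insp_`, `mouth_exp_`), plus per-route perturbation features —
about 160 acoustic features (dictionary version 1.0), to which the five
anthropometrics are appended. Families:

* **Spectral**: Welch PSD (256-sample Hann, 50% overlap); six octave-spaced
  band powers over 75–3000 Hz, total in-band power, spectral centroid,
  normalized spectral entropy (1 for flat spectra, small for tones).
* **Higher-order spectral**: direct (segment-averaged FFT) bispectrum on a
  128-point grid; mean/max magnitude and magnitude entropy over the
  principal region, and mean squared bicoherence
  `|B|² / (E|X(f1)X(f2)|² · E|X(f1+f2)|²)`, which approaches 1 under
  quadratic phase coupling.
* **Time-domain**: Higuchi (k_max = 8) and Katz fractal dimensions,
  zero-crossing rate, envelope-peak count/mean/SD.
* **Time–frequency**: 4-level periodized Symlet-4 DWT (energy conserved
  exactly; relative energy and normalized log-energy entropy per sub-band)
  and a constant-Q filterbank (12 bins/octave over 75–3000 Hz) summarized
  as mean log energy per octave. The constant-Q step is an energy summary,
  not an invertible transform — only energies are consumed downstream.
* **Nonlinear dynamics**: RQA (embedding dimension 3, delay at the first
  autocorrelation zero, radius at the distance quantile giving 10%
  recurrence) on the phase decimated to ≤ 300 samples: recurrence rate,
  determinism, laminarity, longest diagonal; plus the largest Lyapunov
  exponent by Rosenstein's method, with the divergence regression starting
  at step 0 so the immediate separation of stochastic signals is captured.
* **Perturbation**: cycle marks from amplitude-envelope peaks refined to
  burst energy centroids (raw argmax positions wander on flat envelope
  plateaus and would masquerade as jitter); local jitter
  `mean|T_i − T_{i+1}|/mean T` and local shimmer on peak amplitudes.

Failed features are explicit missing values, never silent NaN. Scale
behaviour is tested: entropy, bicoherence, fractal dimension, RQA measures
and relative wavelet energies are amplitude-invariant; band powers scale
quadratically.

# Table preparation and selection

* **Imputation**: stratified k-NN (k = 3) within severity strata, Euclidean
  distance on the stratum's fully observed standardized features; strata
  with at most k donors fall back to the stratum mean with a warning. Donor
  statistics can be restricted to training rows. Note that stratifying the
  imputation by severity uses the label; this mirrors the published
  procedure and is why the package also restricts donors to training rows
  inside the pipeline.
* **Adaptive normalization**: per feature, four candidate scalings
  (z-score, min-max, mean-range, robust) are scored by plug-in mutual
  information (equal-frequency binning, 10 bins) between the scaled column
  and the labels; the argmax is kept with ties broken z-score > robust >
  mean-range > min-max. With equal-frequency binning all four monotone maps
  tie by construction, so the preference order usually selects z-score;
  equal-width binning (a config option) makes the schemes genuinely differ
  under outliers. The mechanism is retained as published; the tie-break is
  this package's documented choice.
* **Selection** (per one-vs-one task, on its own binary labels): Welch
  t-test filter at alpha = 0.05 (no multiplicity correction, both
  configurable); SHAP ranking by mean |TreeSHAP| from a gradient-boosted
  tree ensemble; recursive feature elimination scored by 3-fold CV balanced
  accuracy of a RUSBoost-style ensemble (AdaBoost.M1 over shallow CART
  trees with per-iteration random undersampling of the majority class),
  dropping the weakest 10% of remaining features per step (at least one)
  down to 30 acoustic features. The five anthropometrics are appended
  afterwards and are never eliminated, giving the fixed 30 + 5 = 35-column
  per-task design.

# Base models, stacking, and conformal calibration

Six one-vs-one tasks (all class pairs in severity order) are trained as
B-member bagged ensembles (default B = 50; desk-scale runs use less). The
candidate families are logistic regression, linear and RBF SVM, random
forest, a small MLP, and RUSBoost-style boosting; each family's
hyperparameters are tuned by a Gaussian-process expected-improvement search
(default budget 25 evaluations) scored by out-of-bag (OOB) balanced
accuracy, and the best family wins the task. Every bag member records its
bootstrap rows; OOB scores for a row average only members that excluded it,
and the tests audit this by index.

The meta-model consumes the 12 pairwise probabilities (two complementary
values per task, pairs summing to 1). For its own training rows the
pipeline substitutes OOB scores — stacking leakage control; unseen rows get
full-bag scores. Both class schemes reuse the same six base models; the
three-class scheme only relabels the meta target (a config flag could
restrict to three pairwise models, but the 12-score interface is fixed
before the scheme is chosen). Meta candidates are an MLP, multinomial
logistic regression, random forest, and RBF/polynomial SVM, selected on an
internal stratified validation split. The default MLP follows the anchored
configurations: two hidden layers at learning rate 7.06e-2 for three
classes, three hidden layers at 5.14e-3 for four classes; hidden widths
(16, 16[, 8]), ReLU, Adam, early stopping on a 15% validation split are
this package's choices where no architecture details are anchored.

**Conformal prediction.** A stratified 20% of the training rows is held out
for calibration before any model fitting. Nonconformity is
`s(x, y) = 1 − p(y|x)` with probabilities from the *deployed* meta-model
(OOB predictions serve only internal diagnostics, never calibration —
where the source methodology is ambiguous on this point, the workflow
diagram's separation is followed and the alternative is a config choice).
The threshold is the `ceiling((1−alpha)(n+1))`-th smallest calibration
score with `Inf` appended — the standard finite-sample-valid convention —
and the prediction set contains every label with score at or below it.
Empty sets are allowed and count as misses, preserving the guarantee.
Stratifying the calibration split is this package's choice (a plain random
holdout could leave the 30-subject mild class out of calibration
entirely).

# Evaluation machinery

Accuracy, macro sensitivity and macro specificity (percent), per-class
one-vs-rest AUC, fold summaries as mean ± sample SD, percentile bootstrap
CIs (B = 1000), repeated independent trials (default 25 — the upstream
description is internally inconsistent between 25 and 15, so the count is a
parameter), and learning curves over training fractions {0.2, …, 1.0}
against a fixed test set. Classifier comparisons use the paired t-test and
Wilcoxon signed-rank on per-sample correctness, an exact-binomial McNemar
test on discordant pairs (preferred over the chi-square approximation at
n ≈ 30), Cohen's d in its paired (d_z) form, Cliff's delta by pair counts,
and Bonferroni adjustment over the six meta-vs-base comparisons
(threshold 0.05/6 ≈ 0.00833).

# Numerical choices and degenerate inputs

* Zero-variance features: never scaled (flagged), removed by the t-test
  filter (p = 1 by convention), and fractal dimensions/RQA return missing.
* Bootstrap resamples are redrawn (up to 20 times) if a draw lacks a class.
* Probability outputs use each family's native calibration (sigmoid on SVM
  decision values), so all 12 scores live in [0, 1].
* MI estimates carry the plug-in bias ≈ (bins−1)(classes−1)/(2n ln 2); it
  is identical across candidate scalings, so scheme selection is unaffected,
  and the tests compare against permutation nulls rather than zero.
* All randomness flows from a single seed through a splitmix-style child
  seed derivation, keeping every derived seed a valid 32-bit R seed.

# Problem sizes used in tests and reproduction runs

The suite and the acceptance script size simulations for a desk machine:
test audio cohorts use 8 kHz sampling (the 75–3000 Hz analysis band fits
comfortably) and 2–12 subjects per class; the conformal coverage study runs
500 independent feature-level cohorts of n = 120 (class sizes 45/21/30/24,
proportional to the reference cohort) with lean learners (bagged logistic
bases, multinomial meta), which leaves the coverage guarantee untouched
since it depends only on calibration/test exchangeability; the
design-width check runs the full audio pipeline on 12 subjects per class.
Defaults in `runConfig()` (16 kHz, class sizes 74/35/50/40, B = 25) are the
intended study-scale settings.

# Known limitations

* Synthetic acoustics are schematic; absolute performance numbers on
  generated cohorts say nothing about clinical accuracy.
* The exact published feature inventory is not reproducible from public
  information; the dictionary here is a faithful, versioned realization of
  the named families, not a numeric clone.
* Marginal conformal coverage is guaranteed; class-conditional coverage is
  not (no Mondrian variant).
* The candidate-classifier zoo is a representative six-family reduction of
  a larger unpublished set; the selection protocol, not the zoo's identity,
  is the reproducible object.
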