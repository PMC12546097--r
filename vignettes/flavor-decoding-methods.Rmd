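---
title: "Decoding flavor intensity from tasting-trial EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding flavor intensity from tasting-trial EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Descriptive sensory analysis asks trained tasters to score attributes such
as bitterness, sweetness, acidity and astringency on a 0–10 scale. Those
self-reports are subject to well-known physiological and psychological
biases, which motivates decoding the perceived intensity directly from
brain activity recorded while the taster holds the liquid in the mouth.
`flavorboost` implements that decoding pipeline end to end: EEG feature
extraction, dataset assembly, a boosted-tree regressor selected jointly
with its preprocessing by Bayesian optimization under
leave-one-subject-out (LOSO) cross-validation, benchmark comparison by
Cohen's *d*, and feature-importance topography. Because no raw tasting EEG
is publicly deposited, the package also ships a synthetic tasting-panel
generator with the statistical structure the analysis assumes, so every
stage is testable from a single seed.

## The virtual panel

`panel_config()` fixes the study design: 15 panelists; a 60 s eyes-closed
baseline; two phases — reference water solutions (Be) and coffee blends
(Co) — of four tasting trials each; per trial a 10 s water-rinse (WR)
epoch and a 10 s tasting (TL) epoch; and post-trial 0–10 ratings of the
four attributes. Each virtual subject carries an age (uniform 24–59 y), an
expertise group (trained/expert, 50:50 by default), a true alpha peak
frequency (uniform 8.5–11.5 Hz) and latent attribute intensities per
(phase, trial, attribute), uniform on [1, 9] so that rating clipping at
the scale ends stays rare.

The signal model emulates *cleaned*, band-limited (0.1–40 Hz) scalp EEG:
each of the 38 10-10 channels carries broadband noise with one-sided
spectrum `noise_amp^2 * (1/f + 0.01)` (complex-Gaussian spectral shaping,
inverse FFT), and the occipital channels additionally carry an alpha
oscillation at the subject's true alpha frequency, amplitude-modulated at
0.3 Hz (depth 0.2). The default alpha amplitude (3 µV against a unit-scale
background) gives the strong eyes-closed occipital alpha typical of
resting recordings and keeps the alpha-band center of gravity close to the
true peak. Artifacts (blinks, muscle, line noise) are deliberately absent:
the generator models post-cleaning data, and the published artifact
removal chain is out of scope.

Ratings are `clip(latent + N(0, 1), 0, 10)`: a 1-point rating noise SD is
the within-panelist test-retest variability a sensory panel would accept.
The link from intensity to EEG is the *effect map*: each attribute is
assigned one scalp region and one frequency band, and in TL epochs the
background power of that (region, band) is multiplied by
`1 + 0.1 × intensity` — a 10 % power change per intensity unit, i.e. up to
roughly a doubling at the top of the scale, in line with the magnitude of
task-related band-power modulations reported in tasting studies. The
default assignments are bitter→frontal θ, sweet→central α, acid→parietal
β, astringent→temporal γ. WR and baseline epochs follow the identical law
without the multiplier, which is exactly the contrast the
tasting-vs-rinse normalization later exploits.

What the generator does *not* emulate: volume-conduction correlations
between channels (channels are independent realizations), non-stationary
artifacts, session effects, or any nonlinear coupling between attributes.
Passing tests therefore show that the pipeline recovers effects of the
assumed form at realistic noise levels — not that real tasting EEG
contains such effects.

## Feature extraction

* **Welch PSD** (`welch_psd()`): averaged periodograms with a 1 s Hamming
  window at 50 % overlap, density-scaled so the spectral integral matches
  the time-domain variance (Parseval-checked in the tests). The 1 s window
  gives a 1 Hz grid.
* **Individual alpha frequency** (`estimate_iaf()`): center of gravity of
  the occipital-average (O1, Oz, O2) baseline PSD over 7.5–12.5 Hz.
* **Subject-specific bands** (`define_bands()`): δ = [0, IAF−6],
  θ = [IAF−6, IAF−2], α = [IAF−2, IAF+2], β = [IAF+2, IAF+16],
  γ = [IAF+16, IAF+25] Hz — a contiguous partition of [0, IAF+25].
* **Normalized band powers** (`band_powers()`): PSD integral over each
  band divided by the integral over the full estimable range [0, fs/2].
  Integrals use the trapezoidal rule; a band edge falling between grid
  points is handled by linear interpolation of the cumulative integral, so
  the powers vary continuously with the IAF. A γ band reaching past
  Nyquist is truncated with a warning (not reachable at fs = 512).
* **Hjorth parameters** (`hjorth()`): activity (variance, µV²), mobility
  (square root of the derivative-to-signal variance ratio) and complexity
  (mobility of the derivative over mobility of the signal). Derivatives
  are first differences scaled by the sample rate, so mobility is in
  rad/s (divide by 2π for Hz); the square-root form follows the original
  definition of these descriptors. Complexity is ≥ 1 by Cauchy–Schwarz.

Each epoch yields 304 features (38 channels × 5 band powers + 38 × 3
Hjorth), channel-major. Per trial, the TL vector **x** is normalized
against the same trial's WR vector **y** as `(x − y) ⊘ y` (element-wise),
removing subject- and session-level baselines. Age and the group indicator
(T = 0, E = 1) are appended *after* this normalization — applying it to
them would annihilate them, and expertise/age demonstrably matter for the
prediction. Division is guarded at |y| < 1e−12; synthetic WR features are
bounded away from zero by construction.

Targets are `log(1 + rating)`, the standard variance-stabilizing choice
for ratio scales, with exact inverse `exp(t) − 1`; all MAEs are reported
in transformed units, with `antilog_mae()` mapping them back toward the
rating scale.

## Datasets and standardization

Three feature tables: Be and Co (60 trials × 306 each at 15 subjects) and
their row concatenation BeCo (120 × 306). Subject-wise standardization is
part of the *searched* configuration: z-score, min-max, a robust "median"
variant (median/IQR·1.349 z-score squashed through a logistic into (0,1) —
the published description defers to an external reference, so this
package defines and documents its own robust variant), or none.
Subject-wise means each subject's rows are transformed using only that
subject's statistics, so the transform cannot leak information across a
LOSO split — the tests assert that a subject's standardized values are
invariant to deleting any other subject. Standardization is applied to
the rinse-normalized features (it is searched jointly with the model, so
it must act on the model's actual inputs); a zero subject-level scale
leaves that feature centered only, with one consolidated warning (the age
column always triggers this under z-score, being constant within
subject — a deliberate consequence of subject-wise scoping).

## Models

**LSBoost** (`fit_lsboost()`, compiled core): stagewise least-squares
boosting. F₀ = mean(y); each iteration fits a regression tree to the
residuals and adds it with shrinkage ρ. Trees are exact greedy: every
feature and every midpoint between consecutive distinct values is scored
by squared-error impurity reduction; growth is best-first up to
`max_splits` internal nodes with at least `leaf_min` rows per leaf. Ties
break toward the lowest feature index, then the lowest threshold, and
equal-gain leaves split in creation order — the procedure is fully
deterministic, which the byte-identical-rerun tests rely on. Hyperparameter
bounds: n ∈ [1, 500], ρ ∈ [0.01, 1], leaf_min, max_splits ∈ [1, 100]. A
`leaf_min` too large for the node admits no split, so the ensemble
degenerates gracefully to the constant-mean predictor. Impurity-based
importance sums each feature's gain across all splits of all trees,
normalized to total 1.

**Benchmarks**: the constant mean regressor, and a lasso with the
dimension-based penalty λ = 2·log(p)/n (natural log; ≈ 0.2044 at the
n = 56, p = 306 LOSO fold), under the objective
(1/(2n))·RSS + λ·Σ|β| with unpenalized intercept (glmnet's gaussian
scaling — the convention under which that λ magnitude is meaningful).

## Model selection and evaluation

`bayes_optimize()` solves the joint (hyperparameters, standardizer)
search: 10 initial Latin-hypercube configurations, then a
Gaussian-process surrogate (squared-exponential kernel; length-scale by a
small marginal-likelihood grid) with expected-improvement acquisition over
a candidate set of uniform draws plus a local cloud around the incumbent.
The ensemble size, learning rate and leaf size are searched on log scale —
the canonical measure for quantities whose useful values span orders of
magnitude; the number of splits stays linear. Failed evaluations (e.g. a
leaf size exceeding the fold) are recorded as failed trials, imputed at
the worst observed objective for the surrogate, and the search continues.
The objective is the LOSO mean absolute error; each fold holds out all
trials of one subject.

Model-vs-benchmark comparison uses the two-sample pooled-SD Cohen's *d*
on fold MAEs, d = (m_bench − m_model)/√((s²_bench + s²_model)/2), with a
95 % CI from the noncentral *t* distribution (df = 2·folds − 2,
noncentrality d·√(folds/2)); fold MAEs are treated as two independent
samples even though they are paired, following the published construction.
A model is *significant* when both its d against the mean and against the
lasso benchmark are positive with CIs excluding zero. Significant models
are refit on their complete dataset with the optimal configuration; their
normalized importances are collapsed into ten class scores (five band
powers, three Hjorth parameters, age, group — summing to 1 per model) and
a per-channel topography (each channel's eight EEG features summed,
averaged across models), emitted as tabular channel/position/score
records rather than an interpolated scalp image.

## Numerical and design choices

* Integration of PSD bins: trapezoid (rectangle vs. trapezoid is not
  pinned down by the published description); cumulative-integral
  interpolation keeps band powers continuous in the IAF.
* Mobility units: rad/s via fs-scaled first differences (documented so
  users can convert to Hz).
* The Cohen's-d CI is an interpretation: the cited construction is not
  restated in the source, and the noncentral-*t* equal-n form above is the
  textbook version.
* Per-combination searches derive their seeds deterministically from a
  master seed and the (dataset, target) key; epoch and rating noise derive
  from the panel seed and the (subject, task, phase, trial) key. No stage
  touches the global RNG state unseeded.
* Recovery demonstrations run at 20 optimization evaluations on the
  120-trial concatenated dataset — enough for the log-scaled search to
  find competitive configurations in minutes on one core. The wide-band
  couplings (β: 14 Hz) are recovered more strongly than narrow-band ones
  (α: 4 Hz) because band-power estimation noise scales inversely with the
  number of spectral bins averaged; the α-coupled attribute is therefore
  the hardest of the four at matched gain.

## Known limitations

* The GP surrogate is isotropic in the encoded space; an ARD kernel would
  likely need fewer evaluations.
* Fold MAEs are paired across models but compared with a two-sample d
  (per the published formula), which is conservative in the denominator
  and anticonservative in the CI relative to a paired analysis.
* The generator's channels are statistically independent; spatial
  leakage/volume conduction of real EEG would correlate neighboring
  channels and change the effective dimensionality of the feature space.
* Single-session data only: test-retest stability of features and models
  is out of scope.
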