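---
title: "Methods: multi-entropy fusion for forehead-EEG fatigue detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-entropy fusion for forehead-EEG fatigue detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling choices behind the package: the
signal model of the synthetic cohort generator, the preprocessing chain,
the nine entropy estimators and their parameters, the stacking classifier,
the leave-one-subject-out (LOSO) protocol, and the numerical conventions
adopted where the underlying methods leave room for interpretation. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The detection problem

Fatigue alters prefrontal EEG in three measurable ways: spectral power
shifts toward theta/delta; the waveform becomes more regular (lower
sample/fuzzy/spectral entropy); and cross-regional coupling patterns
change. With only the two hairless forehead sites FP1 and FP2 available to
a wearable device, the pipeline compensates for the missing spatial
information by extracting many complementary nonlinear descriptors per
1-second epoch and fusing several weak classifiers.

## Synthetic cohort generator

`generate_cohort()` draws, per subject and state, a two-channel recording:

* **Oscillators.** Each canonical band (delta 1–4, theta 4–8, alpha 8–13,
  beta 13–30 Hz) is a superposition of three amplitude-modulated sinusoids
  with carrier frequencies uniform in the band, random phases, and slow
  (0.05–0.3 Hz) sinusoidal envelopes. Three carriers per band stabilise
  the band's relative power across recordings; a single carrier makes the
  per-recording spectrum too idiosyncratic for within-subject state
  contrasts to be reliable.
* **Noise.** 1/f-power background noise, scaled by a per-state amplitude.
* **Coupling.** FP2 is `sqrt(1 - g^2)` times its own oscillators plus `g`
  times a 2-sample-delayed copy of FP1's oscillatory component, so
  information flows FP1 → FP2 by construction and channel variance stays
  comparable across coupling gains.
* **Subject factor.** A log-normal multiplicative baseline (SD 0.15 on the
  log scale) drawn once per subject and applied to both states, so
  between-subject amplitude variance exceeds the within-subject state
  contrast — the regime that makes LOSO validation meaningful.
* **Streams.** Oscillator structure comes from a per-subject stream shared
  by both states (the state contrast is carried purely by amplitudes,
  noise level and coupling gain); noise realisations come from
  per-(subject, state) streams. All streams are derived from the master
  seed by hashing, so cohorts are bit-reproducible in any generation
  order.

The fatigue state multiplies the normal-state parameters by an
effect-size preset. `moderate` (the default) uses theta ×1.8, delta ×1.3,
alpha ×0.9, beta ×0.8, noise ×0.6, coupling gain ×2 — chosen so that
classification is learnable but imperfect. `strong` (theta ×2.6, delta
×1.5, alpha ×0.8, beta ×0.7, noise ×0.4, gain ×3) is the recovery
condition; `none` makes both states identical and is the null control. No
public effect-size measurements exist for this contrast, so these
magnitudes are conventions fixed once, not calibrations. Base amplitudes
(delta 1.5, theta 1.2, alpha 1.5, beta 0.8 µV; noise 1.2 µV) keep epoch
variance comfortably under the 50 µV² artifact gate for typical subject
factors.

What the generator deliberately does **not** emulate: eye blinks and other
ocular artifacts, electrode drift, ERPs, non-stationary fatigue onset, or
intermediate drowsiness levels. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers the statistical structure
it assumes — not that it reaches any particular accuracy on recorded EEG.

## Preprocessing

Stage order: notch (50 Hz, 4th-order Butterworth band-stop, Q = 30) →
band-pass (1–50 Hz, 4th-order Butterworth high-pass/low-pass cascade) →
wavelet denoising → 1-s epoching → variance gate → per-epoch min–max
normalisation. Two orderings matter:

* The variance gate runs **before** normalisation because its threshold is
  in physical units (µV²); normalising first would destroy them.
* Normalisation is **per epoch** so that no scaling information crosses
  the train/test boundary of the later cross-validation. Per-recording or
  per-subject scopes would be defensible but leak amplitude statistics
  across epochs.

All filters are applied forward–backward (zero phase) so epoch boundaries
are not shifted, with odd-reflection padding to suppress edge transients;
the band-pass subtracts the signal mean first to avoid a DC step at the
edges. The high-pass/low-pass cascade is used instead of a single
band-pass prototype because a 1 Hz lower edge makes the band-pass state
matrix badly conditioned at high sampling rates.

Denoising is db4, 4 levels, soft thresholding with the universal threshold
`sigma * sqrt(2 log n)`, `sigma` estimated as `MAD/0.6745` of the finest
detail level. Estimating `sigma` per level was tried and rejected: at
coarse levels the estimate includes oscillatory signal, the threshold
explodes, and the denoiser flattens the very regularity contrast between
states that the entropy features measure. With two channels, ICA-based
ocular artifact removal is ill-posed, so wavelet shrinkage plus the
variance gate is the entire artifact strategy — a deliberate
simplification.

The wavelet engine itself (used by the denoiser and the wavelet entropies)
is an orthonormal Daubechies filter bank with periodised convolution,
implemented in the package. Signals whose length is not a multiple of
`2^levels` are zero-padded to the next dyadic multiple and truncated after
reconstruction, keeping analysis/synthesis exactly invertible at every
length; 1-s epochs at the common rates (200, 250, 500, 1000 Hz) need no
padding at the feature settings.

## Entropy estimators

All template-matching estimators use the Chebyshev (max) norm — the
literature default. Defaults, applied per channel to each normalised 1-s
epoch:

| Feature | Parameters | Notes |
|---|---|---|
| AE | m = 2, r = 0.7·SD | self-matches included (Pincus) |
| SE | m = 2, r = 0.7·SD | self-matches excluded; `-log(A/B)` |
| FE | m = 2, r = 0.7·SD, n = 2 | mean-centred templates, membership `exp(-(d/r)^n)` |
| K2 | m = 6, r₀ = mean abs deviation | maximum-likelihood escape times, delay 1 |
| PE | s = 2, m = 5, τ = 4 | coarse-grain by window means, normalised by `log(m!)` |
| SPE | 1–50 Hz | single periodogram per epoch (epochs too short for Welch averaging) |
| STE | k = 1 | first-difference binarisation; `STE_ch` is flow *into* ch |
| WLE | db3, 2 levels | leaves ordered [approximation, details deepest→shallowest] |
| WPE | db3, depth 2 | Shannon entropy of leaf energy fractions |

Numerical conventions and degenerate inputs:

* Natural log for AE/SE/FE/K2/PE/SPE/WLE; base 2 for STE and WPE (bits).
* Constant signals return 0 for AE/SE/FE (SD = 0 means the tolerance is
  degenerate; zero is the regularity-limit convention).
* SE with zero length-(m+1) matches returns the guarded upper bound
  `log(B + 1e-10)`, flagged; zero length-m matches is an error.
* K2 fails loudly (an error, never a silent NaN) when no embedded pair
  falls within r₀ or every pair escapes immediately; `-log(1 - 1/b̄)` with
  b̄ the mean number of consecutive steps a pair stays within r₀.
* WLE floors squared coefficients at 1e-12 inside the log.
* PE breaks rank ties by position (first occurrence ranks lower); ties
  have measure zero for continuous signals.
* STE's 2×2×2 plug-in joint table uses explicit factor levels so absent
  symbol combinations contribute zero rather than corrupting the table
  shape; the estimate is clamped at 0 (plug-in TE can go slightly negative
  from finite samples).
* Any non-finite feature value aborts the epoch with the failing feature
  named — estimator failures are errors, not silent NaNs.

The feature vector is 22 values at defaults, named
`<MEASURE>_<CHANNEL>` (e.g. `WLE_2_FP1`, `STE_FP2`), FP1 block first.
Which physical subband the WLE leaf index denotes is a package convention
(documented above), as is the STE direction — both are stated here because
figure labels of the form `STE_FP1` are ambiguous about source and target.
The FFT baseline (`extract_rbp_table()`) is the delta/theta/alpha/beta
fraction of 1–50 Hz periodogram power; the fractions need not sum to 1
because the 30–50 Hz residual is excluded.

## Feature pruning

Pearson pruning at |r| > 0.98, greedy in column order: a feature is
dropped when it correlates above threshold with an *earlier kept* feature,
so the result is deterministic and keep-first. Absolute correlation is
used so strong anticorrelation also triggers removal; zero-variance
features are dropped with reason `"constant"`. Pruning is always fitted on
the training rows of the current fold and the kept-feature list applied
unchanged to the held-out rows. A global-pruning mode is available simply
by calling `correlation_prune()` on a full table, but per-fold is the
default because anything else leaks test statistics.

## Classifiers and stacking

* **Ridge-logistic regression** (glmnet, α = 0, λ = 1/n): the small fixed
  penalty keeps coefficients finite under quasi-separation, which occurs
  regularly inside small LOSO training folds.
* **ELM**: 200 sigmoid hidden units, weights and biases uniform(−1, 1)
  drawn from a derived substream, output weights the closed-form ridge
  solution (λ = 1e-3). The dual (kernel) form of the solution is used when
  rows < hidden units — mathematically identical, numerically far better
  conditioned. Raw outputs are clipped to [0, 1].
* **Gradient-boosted trees** (xgboost backend): 200 trees, depth ≤ 6,
  η = 0.1, logistic loss, single-threaded for determinism.

The stacking ensemble fits all three base learners in 5 stratified inner
folds, collects out-of-fold probabilities into a 3-column meta-feature
matrix, fits a ridge-logistic meta-combiner on it, then refits the base
learners on the full training split for deployment. The out-of-fold
construction is the leakage guard: the meta-combiner never sees a base
probability produced by a model that trained on that row. If a class is
too small for 5 folds the model refolds with a warning. `fusion = "mean"`
replaces the learned combiner with plain averaging — both fusion readings
are legitimate, so both are shipped; the learned combiner is the default.
All hyperparameters above are package defaults chosen for stability at
~20 features and a few hundred training epochs per class; none are tuned
to any dataset.

Every source of randomness (fold assignment, ELM weights, boosting) flows
from one pipeline seed through named hashed substreams, so a fixed seed
reproduces the entire model bit-for-bit.

## Evaluation protocol

"Leave-one-out" is interpreted as leave-one-**subject**-out: each fold
holds out every epoch of one subject and trains on all other subjects'
epochs. Epoch-level leave-one-out would let a subject's own epochs train
their classifier — with strong per-subject baselines that is leakage, and
at ~19k epochs it would also be computationally pointless. Inside each
fold, pruning and z-scoring are fitted on training rows only. The decision
threshold for confusion matrices is fixed at 0.5; ROC curves and AUC
(trapezoidal over the tie-grouped threshold sweep, equal to the normalised
Mann–Whitney statistic) are reported separately. Positive class = fatigue;
sensitivity is the fatigue detection rate. Metrics with zero denominators
are reported as `NA` and excluded from that metric's summary count, not
silently zeroed. Summaries are the arithmetic mean and sample SD (n−1)
across subjects; pooled counts are also reported because subject-mean and
pooled accuracy differ whenever fold sizes differ.

## Problem sizes

The shipped checks run at deliberately reduced scale: the test fixtures
use 4-subject, 20-s cohorts at 200 Hz; the end-to-end recovery study uses
8 subjects × 60-s recordings at 200 Hz (960 epochs per cohort) over five
generator seeds, with one feature extraction shared across channel sets
and the band-power baseline; the epoch-accounting check generates the full
32-subject × 5-minute cohort at 64 Hz, which exercises the exact epoch
arithmetic without the cost of feature extraction. These sizes are the
package's chosen test conditions; nothing in the method depends on them.

## Known limitations

* Two channels only; the preprocessing chain has no ICA stage, no
  reference-channel regression and no streaming mode.
* EDF import is not implemented — recordings enter as CSV plus manifest
  (or programmatically); the synthetic generator writes that format.
* The generator's fatigue contrast is stylised; effect sizes are
  conventions. Accuracies measured on synthetic cohorts say nothing
  quantitative about recorded EEG.
* Entropy parameter sweeps (grid search over m, r, τ, …) are left to the
  user as configuration loops over `entropy_config()`.
* No significance testing between classifiers, no probability
  calibration, and no SHAP-style attribution are included.
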