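---
title: "Hierarchical latent structures for bi-directional fruit spectra reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical latent structures for bi-directional fruit spectra reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomospec)
```

## The method

`tomospec` models a batch of fruits measured twice: once whole, and once per
dissected tissue (skin, pulp, seed), all on a common Vis-NIR wavelength
grid. The central assumption is that the latent structure of the whole-fruit
spectra and the joint latent structure of the tissue spectra describe the
same underlying biology — maturation state, pigment composition, structural
differences — so a bridge between the two latent spaces supports inference
in both directions.

The pipeline is:

1. **Scatter correction.** Each spectrum is log-transformed and regressed by
   ordinary least squares on a reference log-spectrum (the training mean);
   the corrected spectrum is `(y - a)/b`. Multiplicative gains become
   intercepts in the log domain, so the correction is exactly invariant to
   per-sample gain. The reference is fitted on training data only and frozen
   for any hold-out application — refitting it on validation spectra would
   leak hold-out information into the model spaces.
2. **Per-tissue PCA.** Each tissue block is mean-centred and decomposed by
   SVD, `X_j = t_j p_j' + e_j`, keeping `n_sub` components per tissue. The
   same count across tissues keeps the dimension-wise fusion well defined.
3. **Fusion.** For each sub-dimension *i* the three score columns are
   stacked into an n-by-3 block, column-centred, scaled to unit variance
   (so no tissue dominates by score magnitude alone), and decomposed by a
   small SVD: `t_f = T_i P_i'`. The number of fused directions `d_i` (1 to
   3) is the smallest whose cumulative variance reaches
   `fusion_variance_threshold`. Aligned tissue information collapses onto a
   single direction with loading proportional to `(1,1,1)/sqrt(3)`;
   disagreeing tissues keep up to three. The centring and scaling constants
   are stored per dimension, so at threshold 1 the fusion is exactly
   invertible back to the raw stacked scores.
4. **Association.** The whole-fruit block gets its own PCA, `Y = U C'`. Two
   bridges between `T` (concatenated fused scores) and `U` are provided:
   a global linear least-squares pair (`U = T b`, `T = U c`) — the algebraic
   reading — and inverse-distance-weighted k-nearest-neighbour propagation,
   which respects the cluster structure that maturation stages form in both
   spaces and is the default (`k = 5`). The maps are global rather than
   per-dimension: a per-dimension regression would forbid any cross-talk
   between fused dimensions and tomato components, which nothing in the
   model guarantees.
5. **Reconstruction and decomposition.** Tissues → fruit runs projection,
   fusion, `T → U`, and expansion through the tomato basis; fruit → tissues
   runs the reverse. Outputs live on the preprocessed (scatter-corrected
   log) scale, since the per-sample MSC coefficients of an unobserved
   spectrum are unknowable.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_sub` | 8 | components per tissue sub-space; the usual working size for smooth Vis-NIR spectra, and the value `optimize_components_cv()` will lower when the data support fewer |
| `fusion_variance_threshold` | 0.95 | cumulative-variance cutoff for `d_i`; 1.0 makes fusion lossless, lower values drop disagreement directions |
| `mode`, `k` | `"knn"`, 5 | association bridge; `"linear"` is deterministic and exact for genuinely linear data |
| `alpha`, `n_permutations` | 0.05, 200 | level and resolution of the component randomization test |
| `epsilon` (MAPE guard) | 1e-6 | wavelengths where the reference magnitude falls below it are excluded from percentage errors |

Standardization (`(x - mean)/sd`, sample sd with the n−1 denominator)
defaults to the per-spectrum axis because its purpose here is removing
per-sample signal-intensity differences before spectra are compared; the
per-wavelength axis is available where variable rescaling is wanted instead.

## Choosing the number of components

Two sizing tools are provided. `select_components_randomization()` is a
permutation parallel analysis: every wavelength column of the centred matrix
is independently row-shuffled, which preserves each column's marginal
distribution while destroying inter-wavelength covariance, and the observed
variance of component *j* is compared with the `(1 - alpha)` quantile of the
*j*-th component variances of the permuted matrices. The same-index
comparison matters: a sequential scheme that deflates accepted components
and compares the residual's leading eigenvalue against a shuffle of the
residual is noticeably anti-conservative — after a strong component,
eigenvalue repulsion biases the observed residual eigenvalue upward relative
to its shuffled null, and the test keeps accepting noise components at well
above the nominal level. The same-index null absorbs the strong components'
variance into the permuted spectrum and stays conservative.

`optimize_components_cv()` sizes the full pipeline instead: for each
candidate `n_sub` it leave-one-out refits the whole model, decomposes the
held-out whole-fruit spectrum and records the per-tissue mean squared error
`e = [e1, e2, e3]`. The chosen size is the smallest candidate whose summed
CV error is within a relative tolerance (1e-6, plus 1e-12 absolute) of the
minimum: past the informative dimensions the curve flattens, and growing the
sub-spaces only propagates random structure into the superset.

## Quality prediction

`fit_pls()` is a univariate NIPALS implementation with X-and-y deflation;
the coefficient vector is assembled by the oblique projection
`b = W (P'W)^{-1} q`. The LV count minimises the leave-one-out RMSE —
equivalently PRESS, since `PRESS = n RMSE^2`, so the two stated selection
rules share one argmin; exact ties go to the smaller count. At full rank the
predictions coincide with ordinary least squares, which the tests use as an
oracle, together with the identity that the first weight vector is the
dominant eigenvector of `X'y y'X`. `fit_pcr()` and `predict_similarity()`
are the benchmark alternatives.

The benchmark split is stratified by maturation stage: with only a handful
of red fruits in a realistic batch, an unstratified 70/30 split regularly
loses the red class from one side.

Pigment indices are band ratios on *positive, scatter-corrected* spectra:
chlorophyll as mean(520–570 nm)/mean(571–700 nm), lycopene as the
reciprocal, with unweighted means over the grid points inside the closed
bands. Inside `quality_benchmark()` they are computed on `msc_linear()`
output — the exponential of the corrected log spectra — because corrected
log-domain values of order-one intensities are routinely negative and would
break ratio positivity, while standardized spectra always would.

## The synthetic generator

No paired fruit/tissue dataset is publicly deposited, so the package
generates one with the statistical structure the method assumes
(`synth_config()` / `generate_dataset()`, defaults: 118 fruits, 53 green /
60 turning / 5 red, 380–780 nm at 1 nm). Each tissue spectrum is a smooth
positive baseline minus Gaussian absorption bands: chlorophyll features near
480 and 680 nm with depth proportional to `1 - m`, a carotenoid/lycopene
feature near 530 nm with depth proportional to `m`, where `m` in [0, 1] is
the maturation parameter (stage centres 0.1 / 0.5 / 0.9 with within-stage
jitter). The skin carries the strongest pigment signal. A second latent
factor — a structural/size term tilting the baseline — makes the noiseless
data exactly rank two, which is what gives the component-selection tests a
known answer. Measurement artefacts are per-sample multiplicative gain and
additive offset, plus additive detector noise.

The whole-fruit spectrum is mixed from the *noiseless* tissue spectra.
The default mixing is a weighted geometric mean — light attenuates
multiplicatively along its path through the tissues — scaled by an opacity
factor `1 - opacity (1 - m)` that darkens green fruit, whose dense,
pectin-rich tissues transmit less light. The mixing weights receive
per-sample log-normal jitter (sd 0.2): a probe never samples the tissues in
exactly the nominal proportion, and this probe-position variability is the
main reason whole-fruit reconstruction is genuinely harder than tissue
decomposition, reproducing the characteristic error ordering without making
the forward direction trivially linear. A linear (arithmetic-mean) mixing
mode without opacity exists for lossless round-trip checks: combined with
`preprocess = "none"` and full-rank fusion it makes the entire pipeline
linear, so hold-out decomposition must be exact to machine precision — any
defect in the projection/fusion/association algebra surfaces there.

Quality targets are soluble solids content increasing in `m` (4 + 6m %,
noise sd 0.3) and puncture force decreasing in `m` (9 − 6m N, noise sd 0.4),
matching the agronomic pattern of softening, sweetening fruit.

What the generator does **not** emulate: instrument line-shape and detector
response, wavelength-dependent noise, specular artefacts, the jelly
parenchyma and other tissues folded into "pulp" in practice, biochemical
diversity beyond two latent drivers, and any spatial structure. Passing
tests therefore demonstrate the correctness and statistical behaviour of the
algorithms under the stated assumptions — not that a particular instrument
or cultivar will reach any particular accuracy.

## Numerical choices

* Loadings are oriented so each vector's largest-magnitude element is
  positive; SVD is otherwise sign-ambiguous and run-to-run reproducibility
  (bit-identical models for identical seeds) would fail.
* All randomized operations take a seed; internal streams derive sub-seeds
  deterministically from it, keeping every derived seed below 2^31.
* Rank bounds are enforced as `min(n - 1, p)`; requesting more components is
  an error rather than a silent truncation.
* Degenerate inputs fail loudly with classed conditions: non-positive
  intensities before the log transform, MSC slopes below 1e-12, zero
  variance on a standardization axis, zero-variance PLS targets.
* In the fusion, a stacked score column with near-zero spread (below 1e-10,
  e.g. beyond the numerical rank of a noiseless block) keeps scale 1 rather
  than exploding under unit-variance scaling.
* Percentage errors exclude wavelengths where the reference magnitude is
  below 1e-6 and report how many were excluded; standardized spectra cross
  zero, and a single near-zero denominator otherwise dominates the mean.
  Pooled MAPE over all sample-wavelength pairs remains sensitive to
  near-zero crossings, which is why `evaluate_reconstruction()` also
  reports the median per-sample MAPE as the robust summary.

## Problem sizes used in the shipped checks

The test-suite and acceptance script work at desk scale, chosen so the full
pipeline (not a shortcut) runs everywhere quickly: batches of 12–30 fruits
on coarse grids for algebraic identities and leave-one-out sizing, the full
118-fruit default batch (401 wavelengths) for the end-to-end emulation, 100
replicate seeds for the randomization-test operating characteristics and 50
for PLS size recovery.

## Limitations

* Decomposed and reconstructed spectra live on the corrected log scale;
  absolute detector counts of an unobserved spectrum are not identifiable
  because its scatter coefficients are unknown.
* The knn association cannot extrapolate beyond the training cloud; use
  `latent_stability()` to check how far hold-out fruits sit from the
  knowledge base before trusting their reconstructions.
* The linear association assumes a global linear bridge between `T` and
  `U`; strongly nonlinear mixing (high opacity contrast) degrades it
  gracefully but measurably.
* Equal `n_sub` across tissues is a modelling convenience; tissues with
  genuinely different intrinsic dimensionality pay a small price in either
  noise admission or signal truncation.
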