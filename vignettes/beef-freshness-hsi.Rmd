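---
title: "Discriminating fresh, frozen-stored and frozen-thawed beef with hyperspectral imaging chemometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating fresh, frozen-stored and frozen-thawed beef with hyperspectral imaging chemometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beefhsi)
```

## The problem

Repeated freeze–thaw cycling degrades beef: ice crystals rupture cells,
drip loss dehydrates the surface, and heme pigments (hemoglobin,
myoglobin) oxidize to their met- forms, discoloring the meat. The four
states of interest — fresh (`F`), frozen–stored once (`F-S`),
frozen–thawed three times (`F-T-3`) and five times (`F-T-5`) — are hard to
tell apart by eye but leave spectral fingerprints in the visible/near-infrared
reflectance of the cut surface. `beefhsi` implements a complete chemometrics
pipeline for push-broom hyperspectral cubes (400–800 nm, 251 bands) that
classifies cuts among these four states and maps per-pixel deterioration.

The pipeline stages are:

1. **Reflectance calibration** — raw intensity `I0` is converted to
   reflectance with dark (`B`) and 30%-reflectance white (`W`) reference
   frames: `I = (I0 − B)/(W − B) × 0.30`. Detector positions with
   `W − B ≤ 0` are masked.
2. **Tissue segmentation** — every pixel is labeled muscle or fat by the
   smaller Euclidean distance to a standard spectrum of each tissue
   (ties go to muscle; background by mask or a 0.02 reflectance floor).
3. **Preprocessing** — Savitzky–Golay smoothing, first derivative,
   standard normal variate, polynomial detrending, composable in any
   order. The named pipelines are `RAW`, `SG_FD`, `SG_FD_SNV`,
   `SNV_DETREND`.
4. **Wavelength selection** — competitive adaptive reweighted sampling
   (CARS) with an internal cross-validated PLS engine, run independently
   on the muscle and fat mean spectra.
5. **Classification** — PLS-DA (ordinal coding 1–4, ±0.5 assignment
   rule), one-vs-rest RBF SVM, and a three-layer back-propagation network
   (tanh hidden, linear output).
6. **Evaluation** — SPXY 75/25 partitioning, stratified 10-fold
   cross-validation, confusion matrices with ACC/SEN/SPEC, and spectral
   angle mapper (SAM) summaries of between-class spectral change.
7. **Deterioration mapping** — the tissue-specific PLS-DA regression
   score, clipped to [1, 4], rendered per pixel through a blue-to-yellow
   colormap.

## The models, briefly

**PLS1 engine.** All regression steps share a NIPALS PLS1 with
mean-centering and no variance scaling (bands share reflectance units).
At full rank its coefficients equal the least-squares solution, which the
test suite verifies against the normal equations — one oracle anchoring
CARS, PLS-DA and the deterioration index.

**CARS.** Over 50 sampling runs, each run fits PLS on a random 80% sample
subset restricted to the surviving wavelengths, ranks wavelengths by the
normalized magnitude of their regression coefficients, enforces an
exponentially decreasing retention count `r(j) = a·exp(−k·j)` (calibrated
so `r(1) = 1` and `r(50) = 2/251`), and then applies adaptive reweighted
sampling: the retention count is drawn *with replacement* with
probability proportional to the weights, and the distinct draws survive.
The draw count equals the schedule's target count, so the realized
variable-count trajectory tracks the exponential schedule rather than
collapsing geometrically. The subset with minimal 10-fold RMSECV across
runs is selected. The response is the ordinal class code 1–4; the PLS
component cap is `min(10, #variables, n − 1)`.

**Classifiers.** PLS-DA regresses on the ordinal codes and assigns class
`k` only when the continuous score lies strictly within `k ± 0.5`;
anything else is *unassigned* and counts as an error in every metric.
The SVM is four one-vs-rest RBF machines (the one-hot coding) with argmax
decision; `fit_svm()` defaults to the reference hyperparameters
`(C, γ) = (0.18, 0.008)`, but `run_experiment()` follows the original
protocol of selecting `(C, γ)` by stratified cross-validation on the
training set (`tune_svm()`), since good values are data-dependent. The
BP network uses a tanh hidden layer, linear 4-unit output, standardized
inputs, seeded full-batch gradient descent with momentum 0.9 and L2
weight decay 0.005; the decay matters because standardization inflates
uninformative bands to unit scale, and an unregularized net overfits
them.

**Differentiated tissue.** Muscle and fat get independent CARS subsets
and classifiers. A sample's label is the muscle prediction unless its fat
areal fraction exceeds one half, in which case the area-weighted vote
hands the decision to the fat classifier (`muscle_priority` ignores fat
entirely; both strategies are exposed). Cut-level (`overall_average`)
models use the whole-cut mean spectrum instead.

## The synthetic scene generator

No measured hypercubes are distributed with the study this pipeline
models, so the package ships a generator whose output has the structure
the method assumes, making every stage testable end to end.

Endmembers are smooth sigmoid baselines with Gaussian absorption dips
(widths quoted as FWHM, the spectroscopic convention): heme pigments at
420 nm (FWHM 15 nm) and the 550/572 nm oxymyoglobin doublet (FWHM
20 nm), five times deeper in muscle than in fat; oxidation features at
500/650 nm. Deterioration is a continuous latent state `t` (the class
code plus `N(0, 0.1)` scene-to-scene biological variability) that acts
monotonically at every band: pigment dips deepen by per-unit factors
0.10/0.35/0.35 (drip loss concentrates pigments at the surface and
metmyoglobin formation hits the oxymyoglobin doublet hardest), oxidation
dips deepen by 0.01 reflectance per unit, and a gentle global scale
`1 − 0.005 (t − 1)` models dehydration. Because every class effect is
monotone in `t`, two scenes generated from the same seed but different
classes are ordered band-wise, fresh above deteriorated — the ordering
the method's figures rely on. Class-discriminative structure is therefore
concentrated near 420/500/550/572/650 nm, which is what makes CARS's
selections interpretable.

Noise has three scopes, all realistic for a low-cost push-broom system:

* per scene — illumination gain (sd 0.02), absorption-depth jitter
  (2%), and band-wise spectral-response noise, sd 0.004 in the
  mid-range rising by 0.04 toward the spectral edges (below ~405 nm and
  above ~700 nm, where halogen output and detector quantum efficiency
  fall off);
* per pixel — multiplicative scatter (sd 0.02), a random quadratic
  baseline (amplitude 0.01) and additive noise (sd 0.005), the work that
  SNV, detrending and Savitzky–Golay smoothing exist to undo;
* geometry — an elliptical cut with connected fat marbling from a
  thresholded smoothed-noise field, hitting a requested areal fat
  fraction.

`effect_scale` scales every class effect at once: 0 collapses the four
classes (a null-hypothesis regime for stress tests), 1 is the default
study condition.

What the generator does *not* emulate: muscle fiber texture, spectral
smile, shot-noise physics, and any quantitative reflectance level of real
beef (the source study's figures carry no usable axis values, so
magnitudes here are conventions). Passing tests therefore certify the
*pipeline mechanics* — calibration algebra, segmentation logic, selector
behavior, classifier wiring, leakage-free evaluation — not field
performance on real cuts.

## Numerical and design choices

* Savitzky–Golay defaults to window 5, order 2; edges use truncated
  one-sided least-squares windows so the band count is preserved. The
  first derivative is a forward difference over the wavelength step,
  shortening 251 bands to 250 (midpoint grid).
* Detrending uses degree 2 on a standardized wavelength axis.
* SPXY distances combine predictor-space and ordinal-class Euclidean
  distances, each normalized by its maximum; selection is
  Kennard–Stone on the combined distance, deterministically, with ties
  to the first index.
* The segmentation inequality is implemented as *minimum* distance
  (muscle iff `Dm ≤ Df`); the printed farthest-standard variant is
  available as `strict_paper_rule = TRUE` for auditability.
* Ties in CARS weight ranking break toward the lower band index; all
  Monte-Carlo draws derive from one user seed, so every selection is
  exactly reproducible.
* Deterioration maps score pixels with the *continuous* PLS-DA
  regression value (not the discretized class); scores are clipped to
  [1, 4] with the raw values kept in a diagnostic layer, and pixel
  spectra pass through the same preprocessing as the training spectra.
* SAM summaries pair the fresh class against each processed class by
  default (`consecutive` pairing is available); angles are reported in
  degrees.
* Cross-validation reports use stratified folds on the training set
  only; final models are refit on the full training set, and neither the
  wavelength selector nor any scaler ever sees a test row.

Problem sizes used by the shipped checks: 64×64-pixel scenes with 251
bands, 20 scenes per class for end-to-end classification, 15 per class
(10 paired repetitions) for the differentiated-vs-overall comparison, and
six repetitions of the default dataset for pooled wavelength-selection
summaries — sizes chosen so a full run completes on a laptop in minutes.

## Known limitations

* The generator's class effects are idealized Gaussians; real meat
  spectra have asymmetric, temperature-dependent features.
* The fat classifier is intrinsically weaker than the muscle classifier
  (fat carries 4× shallower pigment features), so samples dominated by
  fat inherit that weaker accuracy — visible when the fat areal fraction
  exceeds one half.
* CARS selection size varies substantially across seeds (roughly 10–90
  of 251 wavelengths); this mirrors the method's real behavior, where
  the minimum-RMSECV subset is a noisy estimator.
* PLS-DA's ±0.5 rule can reject samples near class boundaries; rejected
  samples are counted as errors rather than excluded, which makes
  reported accuracies conservative.
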