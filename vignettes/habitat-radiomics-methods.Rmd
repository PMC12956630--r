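---
title: "Habitat radiomics on CT: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics on CT: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatct)
```

## What this package computes

`habitatct` implements a habitat-radiomics analysis pipeline for
contrast-enhanced CT of solid tumors, with BRCA-mutation prediction in
high-grade serous ovarian cancer as the motivating application. The chain
is:

1. **Preprocessing** — resample image and mask to 1 mm isotropic voxels by
   nearest-neighbor interpolation (preserving the original HU value set)
   and clip intensities to a soft-tissue display window.
2. **Habitat mapping** — compute six voxel-level local features inside the
   ROI (first-order entropy, GLCM difference entropy, GLCM joint energy,
   GLCM joint entropy, NGTDM contrast, and the HU value itself), pool the
   standardized feature vectors over the training cohort, and partition
   them into `k = 5` habitats by k-means. Habitats are spatially coherent
   subregions of distinct local texture — the imaging correlates of
   necrotic, proliferative and stromal compartments.
3. **Feature extraction** — whole-tumor and per-habitat radiomic features:
   first-order statistics, mesh-based shape descriptors (whole tumor only),
   and the GLCM, GLRLM, GLSZM, NGTDM and GLDM texture families, written
   from scratch and validated against brute-force enumeration oracles.
4. **Feature selection** — reproducibility filtering by ICC(2,1) across
   re-segmentations, a per-feature two-sided Mann–Whitney screen
   (p < 0.05, no multiplicity correction), Spearman redundancy pruning
   (|rho| > 0.9), z-score normalization fitted on the training cohort, and
   L1-penalized logistic regression chosen by 10-fold cross-validation with
   the 1-SE rule.
5. **Modeling** — five learners (logistic regression, RBF-kernel SVM with
   Platt-calibrated probabilities, leaf-wise histogram gradient boosting,
   depth-wise gradient boosting, and a single-hidden-layer perceptron) on
   eight feature sets (clinical, whole-tumor radiomic, habitats 1–5, and
   all habitat features combined), giving a 8 x 5 x 2 AUC grid. The
   optimal feature set maximizes the mean training AUC across learners.
6. **Evaluation** — ROC/AUC with tie-aware Mann–Whitney computation, fast
   DeLong tests for correlated AUCs, Youden-threshold confusion-matrix
   metrics, quantile-binned calibration curves, and decision-curve
   analysis.

Because the patient data behind the motivating study are private, the
package ships a synthetic cohort generator that plants known habitat
structure and a known label model, so every stage is testable end to end
and recovery of planted truth is a first-class property.

## The synthetic cohort generator

`generate_tumor_volume()` builds an ellipsoidal tumor whose maximum
diameter is drawn from a configured range (minimum 20 mm — smaller lesions
cannot carry the spatial heterogeneity habitat analysis needs).
Subregions grow from Voronoi sites placed by best-candidate sampling
(compact, sliver-free cells), randomly permuted so no region index is
systematically the central cell, with interfaces perturbed by a smooth
random field (`boundary_wobble`, default 0.10 of the diameter). An
optional additive site bias (`site_bias_sd`) makes planted cell sizes vary
across patients when a wide habitat-composition distribution is wanted.
Each region is filled with a correlated Gaussian HU field with its own
mean, amplitude, and correlation length, over a smooth background field.

The default region palette (means −20/40/100 HU, SDs 4/12/30 HU,
correlation lengths 0.6/0.9/1.3 mm for the first three regions) encodes
the design intent that habitats differ in *local texture*, not only mean
attenuation: short correlation lengths make local-entropy estimates stable
within a region, and the graded noise amplitudes separate the regions by
roughly 1.3–1.6 bits of local entropy. During development we found that
long correlation lengths (several mm) make the local entropy of a single
region strongly bimodal — locally flat patches versus locally sloped ones —
which the k-means step happily splits; realistic recoverable habitats need
texture that is stationary at the scale of the feature kernel.

Clinical covariates are sampled independently from marginal distributions
(truncated normals for age and the two size measurements; Bernoulli rates
for the binary findings; dichotomized CA125 and HE4 categories), with
rates matching a pooled two-cohort HGSOC case series. Only marginals are
modeled because only marginals are available. Labels follow
`logit(p) = intercept + w_f . fractions + w_c . standardized covariates`;
the default plants a moderate composition signal (weights 2.5/0/−2.5) and
weak clinical effects (history of tumor +1.2, solid diameter −0.4 per SD).

What the generator does *not* emulate: scanner- and protocol-specific
noise, contrast-phase dynamics, non-ellipsoidal gross morphology,
inter-covariate correlation, and any real link between imaging phenotype
and genotype. Passing tests therefore demonstrate the pipeline's internal
correctness and its ability to recover planted structure — not clinical
performance on real patients.

## Voxel-local features and the habitat model

Local features are computed over the cubic neighborhood of radius 2
voxels (5 x 5 x 5; the smallest neighborhood giving stable co-occurrence
estimates), restricted to in-mask voxels. The restriction matters: with
volume-wide neighborhoods, every voxel within two voxels of the tumor
surface — easily 40% of a small tumor — carries texture dominated by the
tumor/background interface, so habitat labels would depend on whatever
surrounds the ROI. Mask-restricted neighborhoods make the feature map a
function of tumor tissue alone.

Intensities are discretized into 32 equal-width bins over the in-mask
windowed range; co-occurrences are pooled symmetrically over the 13 unique
3D unit offsets within the neighborhood; entropies are base-2 with
`0 log 0 = 0`. The per-voxel NGTDM contrast uses each voxel's gray-tone
difference against its own in-mask 26-neighborhood. A sliding-window
engine updates histogram, co-occurrence and difference-marginal
accumulators in O(1) per voxel step, so the feature map costs a few
hundred milliseconds for a 10^5-voxel tumor; every value is validated
against per-voxel brute-force enumeration in the test suite.

The habitat model is fitted once on voxels pooled over the training
cohort (capped at 2,000 voxels per patient by seeded subsampling),
standardized to zero mean and unit population SD, and clustered by
k-means with k-means++ initialization and 10 restarts under a fixed seed.
Population-level clustering — rather than per-patient clustering — is what
makes "habitat 3" mean the same tissue class in every patient, which the
habitat-specific models downstream require; test-cohort voxels are
assigned to the learned training centroids. Centroids are relabeled by
ascending mean HU, so habitat 1 is always the least attenuating (most
fluid-like) subregion; exact assignment ties resolve to the smallest
label. A patient may lack some habitats; their features become missing
values, imputed downstream by training-cohort medians so cohorts stay
intact.

Determinism: the fit is bit-reproducible for identical inputs and seed.
Under permutation of the patient list the seeded subsample changes, so
centroids move by O(sampling noise); the suite checks label agreement
(adjusted Rand index > 0.95) rather than bit identity for that case.

## Region features

Region-level discretization defaults to a fixed 25-HU bin width, the
preferred choice for calibrated CT units. GLCM and GLRLM features are
averaged over the 13 directions (not merged-matrix); GLSZM zones are
26-connected; GLDM dependence uses alpha = 0; NGTDM follows the standard
closed forms with contrast 0 for single-level regions and coarseness
capped at 10^6. Shape features (volume, boundary-face surface area,
sphericity, maximum 3D diameter over boundary voxel centers) are computed
for the whole tumor only, because habitat strata may be disconnected.
First-order skewness and kurtosis of a constant region are defined as 0.

The "1,834 features" figure often quoted for pipelines of this kind
depends on an unspecified image-filter inventory; here the feature
inventory is the original-image channel (about 36 whole-tumor and 32
per-habitat features), which is sufficient for every analysis the package
performs and keeps the oracle suite exhaustive.

## The selection cascade

Stages run in a fixed order and produce nested survivor lists: ICC(2,1)
(two-way random effects, absolute agreement, single measurement; both the
inter-observer and intra-observer coefficient must reach 0.8) when reader
tables from re-segmentation are supplied; the Mann–Whitney screen (exact
enumeration when both groups have at most 8 observations, tie-corrected
normal approximation otherwise; constant features get p = 1); greedy
Spearman pruning in descending |rho| order, keeping the member with the
smaller univariate p (ties lexicographic); and LASSO under the 1-SE rule
with stratified, seeded folds. A stage that would empty the feature set
falls back to the previous stage's survivors with a flag — an all-noise
design legitimately selects nothing, and downstream models still need
inputs. No multiplicity correction is applied at the univariate stage by
design; the cascade's type-I behavior (about 5% retention on pure noise)
is itself a tested property.

## Modeling choices

Hyperparameters are fixed, documented defaults rather than tuned values:
LR is plain maximum likelihood; the SVM uses an RBF kernel with C = 1 and
kernel scale 1/(d · mean feature variance), with probabilities from
internal cross-validated sigmoid calibration on training data only; both
gradient-boosting learners run 100 rounds at learning rate 0.1 (leaf-wise
with at most 8 leaves, and depth-wise at depth 3); the MLP has one hidden
layer of 32 units and weight decay 1e-4. Every stochastic component is
seeded, so the AUC grid is a deterministic function of (data, config,
seeds). The clinical feature set is built by the univariate-to-
multivariate logistic screen (p < 0.05 at both stages, with fallback to
all clinical covariates when nothing is significant — a null-signal cohort
still needs a clinical model to compare against).

The optimal feature set maximizes the mean training AUC over the five
learners; ties break toward the higher mean test AUC, then
lexicographically. On the published average-AUC table this rule selects
the combined habitat model (training mean 0.9392).

## Evaluation

AUC uses the Mann–Whitney formulation with half credit for ties, which
equals trapezoidal integration of the empirical ROC (tested to 1e-12).
The DeLong test uses placement values; its variance reduces to the
single-AUC DeLong variance in the self-comparison limit, and its p-values
are checked against a 10,000-replicate paired bootstrap. Classification
metrics freeze the Youden-maximizing threshold on training scores and
apply it to the test cohort. Calibration curves use quantile bins
(default 5) and report a logistic recalibration slope/intercept without
refitting the predictions. Decision curves implement
`NB(p_t) = TP/n − FP/n · p_t/(1 − p_t)` on a 0.01–0.80 grid (step 0.01)
against treat-all and treat-none; `NB_all` vanishes exactly at the
prevalence threshold and a perfect model's net benefit equals the
prevalence below every positive score — both identities are asserted in
the tests.

## Study-condition choices for the built-in experiments

The acceptance experiments run at sizes chosen once as scaled-down study
conditions:

* **Habitat recovery**: cohorts of 40 patients, three planted regions with
  means 60 HU apart (3.2 pooled within-region SDs), tumors 64–80 mm in
  84^3 volumes — comparable to real adnexal masses, and large enough that
  boundary-mixed voxels (whose local features are genuinely intermediate)
  are a minority. Recovered habitat labels are compared with the planted
  map on a 12% row subsample of voxels; local features are exactly equal
  on any subsample, so this estimates the same agreement at proportional
  cost. Expected behavior: adjusted Rand index above 0.8 in at least 9 of
  10 cohort seeds, with interior (non-boundary) agreement near 0.99.
* **Planted-signal ordering**: 100/50-patient cohorts, two planted regions
  with composition weights ±3 and null clinical effects, site bias 0.15 so
  the habitat-composition distribution is wide (oracle AUC ≈ 0.8). The
  combined-habitat model's mean test AUC should exceed the clinical
  model's by more than 0.1.
* **Null control**: zero planted signal with a 200-patient test cohort, at
  which size a null AUC has SD ≈ 0.04 and all 40 grid cells are expected
  inside 0.5 ± 0.15 with high probability; a 60-patient test cohort would
  make that band a coin flip per cell.
* **Cascade null behavior**: 1,000 pure-noise features (u-test retention
  inside the binomial 99% band around 5%) and 25 pure-noise LASSO runs at
  n = 200, p = 50 (median selected-set size 0).

## Known limitations

* Habitat labels near region interfaces are intrinsically ambiguous: a
  5^3 neighborhood straddling two tissue classes has intermediate texture,
  and no per-voxel classifier can resolve it. Recovery quality therefore
  scales with tumor size relative to the kernel.
* The label-fraction coefficients are only identifiable as contrasts
  (fractions sum to one); recovery tests work in contrast space.
* Printed odds ratios from the motivating study's multivariable table are
  not reproducible from its count table under any standard coding, so the
  clinical module's regression output is validated against simulation and
  closed forms instead.
* The calibration intercept/slope are descriptive; no recalibration is
  applied to predictions.
* The window default (level 35 / width 350 HU) follows the soft-tissue
  convention; configurations whose width is implausibly small relative to
  the level are accepted but warned about, since they flatten all texture.
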