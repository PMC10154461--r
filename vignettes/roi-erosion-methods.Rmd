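---
title: "Millimetre-calibrated ROI erosion for CT radiomics: models and methods"
author: "rimshrink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Millimetre-calibrated ROI erosion for CT radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimshrink)
options(rimshrink.verbose = FALSE)
```

## The problem

Unenhanced CT cannot reliably separate lipid-poor adrenal adenomas
(median attenuation around 20 HU) from non-adenomas such as metastases
and pheochromocytomas (around 37 HU): the distributions overlap, so
radiomics models are built on the full 104-feature description of the
lesion. A known failure mode of such models is the *partial-volume
effect*: because of the scanner's finite point-spread function, voxels
at the tumour margin mix tumour and surrounding-tissue attenuation.
These rim voxels contaminate intensity and texture features, and —
worse — make them unstable, because two readers who place the boundary
a millimetre apart sample very different mixtures.

`rimshrink` implements and evaluates a simple remedy: shrink the
region of interest inward by a fixed millimetre-calibrated radius
before extracting features. Four ROI variants are compared throughout:

* `MAX` — the single slice with the largest cross-sectional lesion area;
* `MAX_E` — that slice eroded 3 mm in-plane (x and y);
* `ALL` — the full lesion volume;
* `ALL_E` — the full volume eroded 3 mm in 3D.

## Erosion semantics

Erosion is defined through the exact Euclidean distance transform: a
voxel is retained iff the distance from its centre to the nearest
*background voxel centre*, measured in millimetres using the voxel
spacing, exceeds the radius. This gives a single spacing-aware
definition that behaves identically on anisotropic grids, reduces to
classical binary erosion by a digital ball on isotropic unit grids, and
is covariant under joint rescaling of spacing and radius. Radius 0 is
the identity; ties at exactly the radius are excluded.

One consequence worth noting: at the default 3.75 mm slice spacing, a
3 mm 3D erosion cannot remove a whole axial end slice (its voxel
centres are 3.75 mm from the nearest out-of-slab background centre), so
`ALL_E` removes the in-plane rim but keeps end slices. The in-plane
erosion of `MAX_E`, by contrast, is fully effective. This asymmetry is
a physical property of thick-slice CT, and it is why the single-slice
method benefits most from erosion in the stability analysis.

The maximum-area slice is chosen before erosion and kept (ties broken
toward the smallest z, deterministically). A per-axis box erosion is
deliberately not offered as the default; the ball-structured EDT rule
matches the "shrink inward by r mm" idiom of clinical segmentation
software.

## Feature extraction

Extraction is deterministic and proceeds as: optional window/level
clamp (default 40/400 HU abdominal window) → nearest-neighbour
resampling of image and mask to 3×3×3 mm (output grid sized by
`ceiling(extent/target)`, each output voxel taking the nearest input
voxel centre, ties toward the smaller index) → 18 first-order
statistics → 14 mesh/PCA shape descriptors → fixed 25-HU-bin
discretization anchored at the ROI minimum → 72 texture features from
the GLCM (21), GLRLM (16), GLSZM (16), GLDM (14) and NGTDM (5)
families. No filtered image channels (wavelet, LoG) are used. The
registry is a data file (`inst/extdata/feature_registry.csv`), so the
104-name set is inspectable and swappable.

Conventions that matter for reproducing numbers:

* GLCM/GLRLM use distance 1 and the 13 unique 3D directions with
  symmetric co-occurrence; features are unweighted means over
  directions with at least one valid pair or run.
* GLSZM zones and GLDM dependences use 26-connectivity; the GLDM
  dependence size counts the centre voxel plus its similar neighbours,
  so it is always at least 1.
* Discretization is min-anchored (`floor((x - min)/25) + 1`), hence
  translation invariant in HU.
* Degenerate inputs follow stated limits: a constant ROI has zero
  entropy and skewness/kurtosis defined as 0, GLCM correlation 1, and
  NGTDM coarseness capped at 1e6.
* Percentiles use the linear-interpolation convention (R type 7).

The surface mesh behind the shape features is built by marching
tetrahedra on a lightly mollified indicator field (Gaussian, 0.8 voxel
sd, iso-level 0.5, linear edge interpolation). Meshing the raw binary
field produces a chamfered staircase that overestimates the area of
smooth solids by several percent; the mollifier removes that bias (a
25 mm digital ball yields sphericity ≈ 0.99). ROIs the mollifier closes
off — a single voxel, or a very thin structure — fall back to exact
voxel-face closed forms; for a one-voxel-thick single-slice ROI the
slab interpretation is exact.

## The synthetic phantom

Because no imaging data are deposited with the study this package
reproduces, validation uses a synthetic phantom whose defaults are the
study's stated conditions plus physically motivated choices:

| parameter | default | rationale |
|---|---|---|
| grid / spacing | 64×64×18 voxels at 1×1×3.75 mm | reported slice thickness |
| class attenuation | 20.2 / 37.4 HU | reported pooled medians |
| per-case mean jitter | sd 11 / 6 HU | reported interquartile ranges |
| per-case offset | sd 5 HU | calibration/protocol drift |
| lesion diameter | truncated normal, 24±10 / 35±14 mm, floor 14 mm | reported size distributions and the 1-cm inclusion floor |
| axis anisotropy | ×U(0.85, 1.15) | mildly ellipsoidal lesions |
| texture | Gaussian field, sd 12 HU, correlation 4 / 6 mm | class-dependent heterogeneity |
| PSF sigma | 1.2 mm | FWHM ≈ 2.8 mm, a typical soft CT reconstruction |
| noise | 12 HU white | unenhanced abdominal CT noise |
| rater amplitude | 2 mm | expert boundary disagreement |

The lesion is an ellipsoid voxelized on the grid, filled with the
class mean plus a correlated Gaussian random field (white noise
filtered with a Gaussian kernel of the stated correlation length and
standardized — chosen over other stationary fields because it is
exactly seedable and fast; the correlation *shape* is not a binding
assumption anywhere downstream). The whole volume is blurred with an
isotropic-in-mm Gaussian PSF (per-axis sigma divided by spacing, so
thick slices blur realistically) and white noise is added. The
ground-truth mask is the pre-blur ellipsoid, so the blur creates true
mixed-attenuation rim voxels inside the mask.

The second rater is simulated by displacing the mask boundary with a
smooth random field: a voxel flips iff its signed Euclidean distance to
the boundary is below the local field value. The field is a
unit-variance smooth field squashed through `amplitude * tanh(0.6 x)`,
so the maximum displacement is strictly below the amplitude (voxels
farther than the amplitude never change) while the typical displacement
is about half of it.

Class separation was calibrated once so the full pipeline attains a
hold-out AUC near 0.9 at 50 cases per class, and then frozen; it is
not a per-experiment tuning knob. All sampling uses the Mersenne-
Twister/inversion generator recorded in the config, and per-case seeds
derive from the master seed, so cohorts are bit-reproducible across
platforms.

What the phantom does *not* emulate: anatomy around the lesion,
scanner-specific noise spectra, beam hardening, intra-lesion necrosis
or calcification, and genuinely independent human re-segmentation.
Passing the phantom battery therefore shows that the pipeline detects
and corrects partial-volume contamination of the stated magnitude under
controlled conditions — not that the clinical effect sizes transfer.

## Stability screening and the selection cascade

Feature stability is screened with the two-way random-effects,
absolute-agreement, single-rater ICC — the standard inter-rater form;
absolute agreement is used because a systematic shift between raters is
a real disagreement for a diagnostic feature. Features with ICC < 0.75
are excluded. Inside the pipeline the screening uses a seeded subset of
at most 50 cases with second-rater masks, mirroring a re-segmentation
study design; the subset size is recorded in the run manifest.

Selection then proceeds in nested stages on training rows only:

1. **Univariate**: two-sided Mann–Whitney U per feature, keep P < 0.05.
   A uniform rank test is used for all 104 features rather than a
   per-feature normality decision; for skewed radiomics features this
   is the conservative choice.
2. **RFE**: recursive feature elimination with an L2-regularized
   logistic base learner on standardized features, dropping the
   smallest-|coefficient| feature per round, down to `ceiling(30%)` of
   the entering set (applied to the post-univariate set, following the
   stage order). The ridge fit involves no resampling, so this stage is
   deterministic.
3. **LASSO**: L1-penalized logistic path with stratified tenfold CV of
   the binomial deviance; the penalty is the largest lambda within one
   standard error of the minimum (the classic 1-SE rule). If that
   lambda zeroes everything, the minimizing lambda is used and logged.

The final logistic model is a maximum-likelihood fit on the surviving
standardized features; its linear predictor is the radiomics score. On
separation the fit is stabilized with a small ridge penalty (lambda
1e-3) and flagged. Standardization constants always come from training
rows; the test suite re-derives validation scores from stored artifacts
to assert the absence of leakage.

The 8:2 split is stratified with floor sizing: 237 cases yield 189
training and 48 validation cases.

## Evaluation battery

* **AUC** by the tie-corrected rank estimator, 95% CI by DeLong's
  structural-components variance (cross-checked against an independent
  implementation in the test suite).
* **pAUC** over specificity ≥ 95%, reported unstandardized (maximum
  0.05): the trapezoidal area of the empirical ROC restricted to
  FPR ∈ [0, 0.05] with linear interpolation at the boundary. All tied
  scores give the diagonal's 0.00125. The CI is a seeded stratified
  bootstrap (2000 replicates by default).
* **Operating points**: Youden-optimal (ties toward higher
  specificity) and the smallest threshold with specificity ≥ 0.95.
* **McNemar** on paired correctness restricted to positive cases
  (sensitivity comparison): exact two-sided binomial when the
  discordant count is below 25, continuity-corrected chi-square
  otherwise.
* **Pairwise score comparisons**: per class, two-sided Wilcoxon
  signed-rank over the six method pairs, Bonferroni-multiplied by 6 and
  capped at 1.
* **Decision curves**: net benefit `TP/n − FP/n · t/(1−t)` on a 0.01
  grid (t = 1 excluded) with closed-form treat-all and treat-none
  references.

The report is a pure function of scores and labels, so every number in
it can be recomputed from the serialized score tables.

## Study conditions used by the automated checks

The acceptance checks run the pipeline end to end at sizes chosen to
be statistically meaningful while completing quickly: 20 replicate
cohorts of 60 cases per class with an 8:2 hold-out for the
method-ranking and ICC-direction checks; 50 phantom replicates at PSF
sigma 2 mm for the partial-volume recovery rate; 50 random two-rater
tables for the ICC oracle; and 20 planted-feature tables (3 informative
among 104, effect 1.5 sd, 100 cases per class) for selection recovery.
`scripts/acceptance.R` recomputes the same quantities at 6 replicate
cohorts.

## Known limitations

* Erosion semantics of the vendor tool being emulated are not
  published; the EDT realization here is the standard one, and a
  per-axis alternative would change `ALL_E` only at oblique boundaries.
* The 72 texture features are a fixed registry chosen to meet the
  21/16/16/14/5 family counts; other published GLCM subsets exist.
* The phantom's second rater is a geometric perturbation, not a human;
  ICC magnitudes depend directly on the chosen amplitude.
* Single-institution phantoms only: the external-validation arm of the
  original study design (a second institution) is represented by the
  hold-out split, not by a distribution shift.

## A worked example

```{r example, eval = FALSE}
library(rimshrink)
res <- run_pipeline(run_config(n_per_class = 30, seed = 11))
print(compare_methods(res))
```

See the README for the output this prints and how to reproduce the
full acceptance numbers.
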