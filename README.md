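# rimshrink

CT radiomics with millimetre-calibrated ROI erosion.

Lipid-poor adrenal adenomas (unenhanced attenuation ≈ 20 HU) and
non-adenomas (≈ 37 HU) overlap on plain CT, so they are discriminated
with radiomics models built from a 104-feature description of the
lesion. Voxels at the tumour margin, however, mix tumour and
surrounding-tissue attenuation because of the scanner's finite
point-spread function (the partial-volume effect); they contaminate
features and make them unstable between readers. `rimshrink`
implements the modified segmentation strategy that addresses this:
shrink the region of interest inward by a fixed radius (default 3 mm,
calibrated in millimetres via the exact Euclidean distance transform)
before extracting features, and quantify what that buys.

The package provides, end to end:

* **Four ROI variants** per lesion mask — maximum-area single slice
  (`MAX`), full volume (`ALL`), and their eroded counterparts
  (`MAX_E`: 3 mm in-plane; `ALL_E`: 3 mm in 3D) — with spacing-aware
  erosion semantics: a voxel survives iff its distance to the nearest
  background voxel centre exceeds the radius.
* **Feature extraction**: window/level clamp, nearest-neighbour
  resampling to 3×3×3 mm, fixed 25-HU-bin discretization, and 104
  features partitioned 18 first-order / 14 shape / 72 texture
  (GLCM 21, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5), no image filters.
* **Stability screening** by inter-rater ICC(2,1) (two-way random,
  absolute agreement); features with ICC < 0.75 are excluded.
* **Selection cascade**: Mann–Whitney univariate screen (P < 0.05) →
  recursive feature elimination retaining 30% → LASSO-penalized
  logistic regression with stratified tenfold CV and the 1-SE rule.
* **Radiomics signature**: a logistic model whose linear predictor is
  the radiomics score, with `print`/`summary`/`coef`/`predict` methods.
* **Evaluation battery**: AUC with DeLong 95% CI, partial AUC at
  specificity ≥ 95% (unstandardized, max 0.05) with bootstrap CI,
  Youden and spec-95 operating points, McNemar tests on sensitivity,
  Bonferroni-corrected pairwise score tests, and decision-curve
  analysis.
* **A synthetic CT phantom** with class-dependent lesion attenuation,
  size and texture, point-spread blur that creates genuine
  partial-volume rims, noise, and a simulated second rater — the
  validation substrate for everything above.

Volumes and masks are NIfTI (`RNifti`); manifests and feature tables
are CSV; models and traces serialize to JSON.

## Worked example

```r
library(rimshrink)
res <- run_pipeline(run_config(n_per_class = 50, seed = 11))
print(compare_methods(res))
for (m in c("MAX","MAX_E","ALL","ALL_E"))
  cat(m, "mean ICC:", mean(res$icc[[m]]$icc),
      " excluded:", sum(!res$icc[[m]]$retained), "\n")
```

This generates a 100-case phantom cohort (50 per class), derives the
four ROI sets, extracts 4 × 100 feature vectors (plus second-rater
features on a 50-case subset), runs the selection cascade and logistic
fit per method on the 80-case training split, and evaluates on the
20-case hold-out. It prints:

```
<method_ranking> split 'val'
  by AUC : ALL_E=0.840 MAX_E=0.740 MAX=0.730 ALL=0.730 (winner ALL_E)
  by pAUC: ALL=0.0150 ALL_E=0.0150 MAX=0.0100 MAX_E=0.0050 (winner ALL)
MAX   mean ICC: 0.838  excluded: 25
MAX_E mean ICC: 0.918  excluded: 5
ALL   mean ICC: 0.824  excluded: 33
ALL_E mean ICC: 0.930  excluded: 8
```

Reading it: the eroded full-volume ROI gives the best hold-out
discrimination (AUC 0.84 on this seed), and erosion markedly improves
feature stability under simulated re-segmentation — the mean ICC rises
from 0.84 to 0.92 (single slice) and 0.82 to 0.93 (full volume), with
far fewer features falling below the 0.75 exclusion threshold. Both
effects are the package's central claim; averaged over 20 replicate
cohorts the eroded variants win the stability comparison in every
replicate and `ALL_E` attains the highest mean AUC and pAUC.

A thin command-line wrapper with `phantom | roi | extract | run |
compare` subcommands is installed at `inst/cli/rimshrink.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","rimshrink.R",package="rimshrink"))')" \
  compare --n-per-class 30 --seed 7 --out /tmp/rs_demo
```

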