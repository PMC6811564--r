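# lnradiomics

CT radiomics of the primary tumor **and** its metastatic lymph nodes for
predicting loco-regional control after definitive radiochemotherapy of
head-and-neck cancer.

Most radiomics models of treatment response look only at the primary
tumor (PT). Loco-regional control (LRC), however, is a composite
endpoint: the disease is controlled only if the primary tumor *and* the
involved lymph nodes (LN) are controlled. `lnradiomics` implements a
complete, testable pipeline for modeling LRC from both regions:

* **Preprocessing** — removal of ROI contours on artifact-affected axial
  slices with a strict eligibility rule (patients with ≥ 50% of ROI
  volume on artifact slices are excluded), resampling to 3.3 mm cubic
  voxels, a closed soft-tissue HU window of [−20, 180] (out-of-window
  voxels are excluded from intensity/texture analysis, not clamped), and
  merging of all involved nodes into one LN ROI.
* **A 285-feature panel per ROI** — 18 shape, 17 intensity and 72
  texture features (GLCM 25, GLRLM 16, GLSZM 16, NGTDM 5, NGLDM 10,
  IBSI-style definitions), plus the 17 + 72 features recomputed on the
  LLL and HHH subbands of a one-level stationary Haar wavelet transform
  (178 wavelet features).
* **14 lymph-node-distribution (LNPT) features** — statistics of
  PT-to-LN center-of-mass distances (5), their LN-volume-weighted
  variants (2), tumor-volume-normalized variants (2), minimum spanning
  tree gaps between structures via Kruskal's algorithm (2), the number
  of LN clusters by Calinski–Harabasz index (1), and elongation/flatness
  of the combined PT ∪ LN point cloud (2).
* **Feature selection** — per-group bootstrap MRMR (relevance
  = |univariate concordance − ½|, redundancy = mean |Spearman ρ|), with
  the per-run feature count sized by the number of principal components
  explaining 95% of variance, and a 60% selection-rate inclusion rule.
* **Model building** — bootstrap LASSO-Cox (cross-validated penalty,
  60% selection-rate rule, unpenalized refit). The fitted object is a
  classed `rad_cox` model whose linear predictor Σ βⱼ xⱼ is the
  **rad score**. Model variants: the LC rad score (PT features → local
  control), the PT model (PT features → LRC), the mixed model (LC rad
  score + LN features → LRC), the LNPT variant, and a PT + N-stage
  comparison model.
* **Evaluation** — Harrell's c-index on 100 bootstrap resamples of the
  validation cohort (shared resamples across models), paired Wilcoxon
  model comparison, and two risk groups split at the rad-score threshold
  maximizing Youden's J for failure by 18 months, compared by log-rank
  test and Kaplan–Meier curves.
* **Synthetic data** — a phantom generator (superellipsoid PT and LN
  blobs with controllable size/shape/texture/spread, optional streak
  artifacts, NIfTI round-trip) and a proportional-hazards outcome
  simulator with planted coefficients, so every stage is testable with
  known ground truth and no clinical data.

## Worked example

```r
library(lnradiomics)

## feature-level cohort with a planted PT effect on local control and a
## planted LN effect on regional failure
co <- simulate_feature_cohort(n = 250, n_pt = 30, n_ln = 30, seed = 21)
gt <- ground_truth(planted_features  = c(pt_f001 = 1.2, pt_f002 = -1.0),
                   regional_features = c(ln_f001 = 1.2))
y  <- simulate_outcomes(cbind(co$pt, co$ln, co$lnpt), gt, seed = 22)

cfg <- pipeline_config(features = co, clinical = y, seed = 5,
                       selection = selection_config(n_bootstrap = 100),
                       lasso = lasso_config(n_bootstrap = 50))
res <- run_pipeline(cfg)

res$models$mixed_ln
#> Radiomic Cox model (endpoint LRC)
#>   2 feature(s), training c-index 0.742
#> lc_rad_score      ln_f001
#>       0.8905       0.6450

round(c(pt = res$evaluation$pt_model$mean,
        mixed = res$evaluation$mixed_ln$mean), 3)
#>    pt mixed
#> 0.751 0.791
res$evaluation$wilcoxon_mixed_vs_pt
#> [1] 1.095622e-17
```

The pipeline recovered the planted structure: the LC rad score is built
from the two planted PT features, the mixed model adds the planted LN
feature, and its validation c-index (0.791, mean over 100 bootstrap
resamples) exceeds the PT-only model (0.751) with a tiny paired
Wilcoxon p-value — the expected behavior when regional failures carry
information that PT features cannot see.

Image-level use is identical, with `phantom = phantom_spec(...)` (or
`cohort_dir =` for NIfTI volumes plus a clinical CSV) instead of
`features =`; the pipeline then runs preprocessing and the full
285-feature extraction first. Per-ROI extraction is also available
directly via `extract_all()`, `extract_shape()`, `extract_texture()`,
`extract_lnpt()` and friends.

## Documentation

The methods vignette (`vignettes/lnradiomics-methods.Rmd`) describes the
model, every tunable parameter with its default and rationale, the
synthetic-data design, numerical conventions, and known limitations.
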