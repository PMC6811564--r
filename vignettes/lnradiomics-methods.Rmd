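---
title: "Methods: combined primary-tumor and lymph-node CT radiomics for loco-regional control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined primary-tumor and lymph-node CT radiomics for loco-regional control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modeling problem

Loco-regional control (LRC) after definitive radiochemotherapy of
head-and-neck cancer is a composite endpoint: a loco-regional failure is
either a local failure (regrowth of the primary tumor, PT) or a regional
failure (progression of involved lymph nodes, LN). A radiomic model
built only on the primary tumor can at best capture the local component.
`lnradiomics` implements the alternative: extract quantitative imaging
features from the PT region, from the merged LN region, and from the
*spatial arrangement* of the nodes around the tumor (LNPT), then combine
them in a two-stage Cox model.

The modeling chain is

1. a **LC rad score**: PT features are selected and fitted against local
   control (LC); the Cox linear predictor Σ βⱼ xⱼ becomes a single
   scalar risk covariate;
2. a **mixed model**: the LC rad score enters a second selection/fit
   against LRC together with the LN (or LNPT) candidates, as an
   ordinary covariate with no special status;
3. comparison models: PT features fitted against LRC directly (the
   PT model), and the LC rad score combined with ordinal N stage.

This staging encodes the biology: the rad score summarizes everything
the primary tumor says about its own control, and the second stage asks
what the nodes add for the composite endpoint.

## Preprocessing conventions

* **Artifact handling.** Dental/metal streaks corrupt whole axial
  slices. ROI contours on recorded artifact slices are removed before
  feature extraction; a patient is *eligible* only when the ROI volume
  on artifact slices is strictly below 50% of the total ROI volume. The
  fraction is evaluated on the combined PT ∪ LN region by default
  (config `eligibility_scope = "per-roi"` switches to the stricter
  per-region variant), and on the original masks, before any removal —
  adding artifact slices can therefore never rescue an ineligible
  patient.
* **Resampling.** Trilinear interpolation to 3.3 mm cubic voxels
  (`target_spacing`), masks re-binarized at 0.5. Voxel centers sit at
  `index × spacing` from a common origin, so physical extent is
  preserved to within one voxel per axis. Convex ROIs with diameter at
  least three target voxels conserve volume to within 15%.
* **HU window.** The closed interval [−20, 180] restricts analysis to
  soft tissue. Out-of-window voxels inside the ROI are *excluded* from
  intensity and texture computation rather than clamped — clamping
  would inject artificial modes at the window edges and change every
  histogram feature. Shape features always use the full mask. The
  window is applied after resampling by default
  (`window_before_resample` swaps the order).
* **LN merging.** All involved nodes form one LN ROI for the
  285-feature panel; 26-connected component labels are retained for the
  LNPT features.

## The 285-feature panel

Per ROI: 18 shape + 17 intensity + 72 texture features on the original
image, and the 17 + 72 recomputed on the LLL and HHH subbands of a
one-level stationary Haar transform (178), totalling 285. The texture
family split is GLCM 25, GLRLM 16, GLSZM 16, NGTDM 5, NGLDM 10; the
manifest is data, so an alternative 72-feature roster is a configuration
change, not a code change.

Numerical conventions that matter:

* **Discretization**: fixed bin size of 5 HU anchored at the window
  floor (−20), i.e. at most 40 grey levels; the top window edge joins
  the last bin. Fixed bin *size* is the standard choice for CT because
  it keeps bin boundaries aligned across patients. Wavelet subbands
  have no absolute scale, so they are re-binned per ROI with a fixed
  count of 40 bins over their own range.
* **GLCM**: 13 symmetric direction offsets at Chebyshev distance 1; the
  13 per-direction probability matrices are averaged before feature
  computation. GLRLM counts are merged over directions; GLSZM zones use
  26-connectivity; NGTDM/NGLDM use the full 26-neighbourhood, NGLDM
  with dependence tolerance 0 (exact level match).
* **Degenerate ROIs**: a single-grey-level region yields entropy-type
  features of 0 and analytic limits for ratio-type features (e.g. GLCM
  angular second moment 1), never NaN — constant phantoms must not
  poison downstream selection.
* **Wavelet kernel**: stationary Haar, separable, edge replication.
  Haar makes the impulse and DC oracles exact: a constant c maps to
  2√2·c in LLL and to 0 in HHH. The transform runs on the ROI bounding
  box, which must span at least the 2-voxel filter support per axis;
  thinner ROIs raise an error naming the axis.
* **Shape**: surface area and mesh volume come from a marching-
  tetrahedra mesh of the 0.5 isosurface of the box-smoothed binary
  mask. Smoothing places the surface at sub-voxel positions and brings
  digital-ball sphericity within ~1% of the continuum; its cost is that
  blobs only a few voxels across lose mesh volume (the voxel-count
  volume is a separate feature and unaffected). Axis lengths are
  4√λ of the voxel-coordinate covariance eigenvalues; elongation and
  flatness are √(λ₂/λ₁) and √(λ₃/λ₁). Local thickness is twice the
  Euclidean distance transform at medial voxels (local EDT maxima) —
  chosen as a transparent, oracle-testable stand-in for proprietary
  thickness definitions in clinical radiomics software.

## The 14 LNPT features

All distances are Euclidean in physical space (mm); every statistic
uses the population SD convention so single-node patients give 0 rather
than NaN.

| group | n | definition |
|---|---|---|
| COM distances | 5 | mean, SD, median, min, max of PT-COM to LN-component-COM distances |
| volume-weighted | 2 | LN-volume-weighted mean and SD of the same distances |
| tumor-normalized | 2 | Σ dᵢvᵢ / V_PT and the population SD of the terms dᵢvᵢ/V_PT |
| MST gaps | 2 | mean and max edge weight of the minimum spanning tree over {PT, LN₁, …}; edge weight = closest surface-voxel-center distance |
| cluster count | 1 | k maximizing the Calinski–Harabasz index of k-means over all LN voxels, k = 2…6 |
| PCA anisotropy | 2 | elongation and flatness of the PT ∪ LN point cloud |

Two definitions were genuinely open and are fixed as follows:

* **Tumor normalization** scales the weighted terms by 1/V_PT so that
  doubling the tumor volume halves the feature. A normalization that
  cancelled in the weighted mean would duplicate the unnormalized pair,
  which would make the two feature groups identical — the chosen form
  is the only reading under which both groups carry information. When
  V_PT equals the total LN volume the normalized mean coincides with
  the weighted mean, which pins the formula in a test.
* **Cluster count at k = 1.** The CH index is undefined for one
  cluster, yet a solitary nodal mass must report 1. The guard is
  geometric: if the two k = 2 clusters are separated by less than twice
  the point pitch (median nearest-neighbour distance), the split runs
  through contiguous tissue and the count collapses to 1. This is
  robust for any number of genuinely separated nodes, unlike
  centroid-distance guards, which misfire when several nodes fall into
  one k = 2 cluster.

The MST includes the PT as a vertex by default (`include_pt = FALSE`
restricts to nodes only). Surface distance uses boundary voxel centers;
sub-voxel meshes would not change the ordering of any phantom fixture
and cost considerable complexity.

## Feature selection

MRMR runs separately for PT, LN and LNPT candidates — redundancy is
never computed across groups. Per bootstrap resample (full size, with
replacement; event-free resamples are redrawn and logged):

* **relevance** of a feature is |c − ½| where c is the univariate
  concordance of the feature with the endpoint. For a survival outcome
  this is the natural analogue of univariate discriminative power, is
  monotone-invariant, and needs no model fit. (A Cox Wald-z variant is
  available by config.)
* **redundancy** is the mean |Spearman ρ| against the already-selected
  set; the greedy score is relevance − redundancy (difference form,
  robust when redundancy is near zero). Ties break lexicographically.
* the per-run feature count k is the number of principal components
  explaining 95% of the variance of the z-scored training matrix,
  computed per group. Radiomic panels are massively redundant — most
  features are near-duplicates of a few latent dimensions (volume,
  intensity level, coarse texture) — so this rule typically yields a
  small k.

Features ranked in ≥ 60% of 1000 resamples (package default; tests use
scaled-down counts, see below) form the selected set. Raising the
threshold can only shrink the set; identical seeds reproduce identical
results bit for bit.

## Model building and evaluation

Candidates (MRMR survivors, plus the LC rad score or N stage where
applicable) are z-scored with training statistics that are frozen into
the fitted object and reused verbatim for validation data — validation
outcomes are never touched by standardization, PCA sizing, selection,
or threshold fitting. Per LASSO bootstrap resample an L1-penalized Cox
path is fit with the penalty chosen by 5-fold cross-validated partial
likelihood; features with nonzero coefficients in ≥ 60% of 100
resamples are refit unpenalized to give reportable coefficients. An
empty surviving set is a *reported* outcome ("training unsuccessful"),
not an error: discarding a whole candidate group is a legitimate and
informative result for comparison models. Perfectly rank-correlated
candidates are dropped pre-fit to avoid coefficient splitting.

The cross-validated penalty is `lambda.min` by default. The stricter
`lambda.1se` rule is the right switch when the scientific question is
"does this candidate group add anything at all": under `lambda.min`
weak noise can retain nonzero coefficients in over 60% of resamples,
while `lambda.1se` reliably discards pure-noise groups against a strong
forced covariate. The group-discard tests use that switch.

Evaluation: Harrell's c-index of the rad score on 100 bootstrap
resamples of the validation cohort, with the same resamples shared
across models so the Wilcoxon comparison is paired; ties count ½, and
resamples without comparable pairs are redrawn. Risk stratification
fits the rad-score cut maximizing Youden's J for failure by 18 months
on the *training* cohort only (patients censored event-free before the
landmark are excluded from threshold fitting — counting them as
non-events is available by flag), then applies the frozen cut to the
target cohort with a two-sided log-rank test.

## Synthetic data: what it emulates, what it does not

`generate_cohort()` builds per-patient volumes with one PT blob and 1–5
LN blobs: superellipsoids with random axis ratios, exponents and rigid
rotations (semi-axes rescaled so the analytic volume matches the
requested volume-equivalent radius), disjoint by at least one voxel,
filled with smooth Gaussian HU texture (default mean 60, SD 20 —
contrast-enhanced soft tissue) on an air background. A configurable
fraction of patients receives extreme-HU streak slices recorded in the
metadata, which is what the eligibility rule acts on. Default grid
64×64×52 at 1 mm.

`simulate_outcomes()` draws local failure times from an exponential
proportional-hazards model whose linear predictor is a known function
of chosen (z-scored) features, an independent exponential regional
clock driven by LN features, LRC time = min(local, regional), and
shared independent exponential censoring — so every local failure is a
loco-regional failure by construction, and Cox fits are well-specified,
enabling coefficient- and selection-recovery tests. Defaults (baseline
0.02/month local, 0.012/month regional, censoring 0.015/month) give
roughly 50–60% LC events and a realistic excess of LRC over LC events
at a median follow-up of a few years.

`simulate_feature_cohort()` skips imaging entirely: each feature group
is a few independent candidate columns plus redundancy blocks of
near-duplicates (base signal + 15% jitter). This mimics the dominant
empirical property of radiomic matrices — extreme mutual correlation
with a handful of latent dimensions — and is what gives the PCA-95%
rule a small k and the MRMR redundancy term real work to do.

What the phantoms do *not* emulate: anatomy (no nodal levels, no organ
boundaries), dose distributions, scanner/protocol variability, partial
volume at contrast boundaries, and observer contouring noise. Passing
tests therefore demonstrate algorithmic correctness and recoverability
of planted effects, not clinical performance.

## Problem sizes in the test suite

The reference procedure uses 1000 MRMR and 100 LASSO resamples; the
package defaults match. The recovery studies in the test suite and the
acceptance script run scaled-down but statistically equivalent versions
chosen once: 200 MRMR / 50 LASSO resamples, cohorts of n = 150 (2
planted among 30 noise features, |β| = 1.5) for selection recovery, and
n = 250 split 60/40 for the mixed-vs-PT comparison, each over 20 seeded
replicates; the image-level smoke test uses 30 phantom patients. Null
calibration uses n = 500 for the c-index center and 200 replicates for
log-rank uniformity.

## Known limitations

* Mesh volume (not voxel volume) is biased low for ROIs only a few
  voxels across, a direct consequence of the smoothing that makes
  surface areas accurate.
* The exact thickness definition and the items 2–4 statistic pairs of
  the LNPT panel are stated stand-ins for definitions that live in
  clinical software supplements; they are pinned by tests so any future
  change is deliberate.
* `lambda.min` vs `lambda.1se` materially changes how aggressively weak
  candidate groups are discarded; both are exposed, and the default
  follows the more common `lambda.min`.
* Evaluation treats the validation cohort as exchangeable with
  training up to the planted effects; there is no domain-shift
  emulation (different scanners, protocols).
* Competing risks and time-dependent covariates are out of scope; the
  regional clock is independent of the local clock given the features.
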