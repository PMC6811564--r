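## Phantom cohort generator: superellipsoid primary-tumor and lymph-node
## blobs with contrast-CT-like soft-tissue intensities, plus linked
## survival outcomes from a proportional-hazards ground truth.

#' Specification of a synthetic phantom cohort
#'
#' Defines the geometry, texture and corruption settings for
#' [generate_cohort()]. All physical quantities are in millimetres and
#' Hounsfield units.
#'
#' @param n_patients Number of patients to generate.
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param spacing Voxel spacing in mm per axis.
#' @param pt_radius_range Range (mm) of the primary-tumor mean radius.
#' @param n_ln_range Integer range of lymph-node counts, within \[1, 5\].
#' @param ln_radius_range Range (mm) of lymph-node mean radii.
#' @param ln_spread Typical distance (mm) between the PT center of mass
#'   and LN centers of mass.
#' @param texture_mode One of `"uniform"`, `"smooth-noise"`, `"two-class"`:
#'   constant HU inside ROIs, spatially smoothed Gaussian texture, or a
#'   two-level mixture.
#' @param hu_mean,hu_sd Mean and spread of ROI intensities (HU).
#' @param artifact_fraction Fraction of patients given streak-corrupted
#'   axial slices (recorded in the per-patient metadata).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including this seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 20L,
                         grid_shape = c(64L, 64L, 52L),
                         spacing = c(1, 1, 1),
                         pt_radius_range = c(7.5, 12),
                         n_ln_range = c(1L, 5L),
                         ln_radius_range = c(4.5, 7),
                         ln_spread = 18,
                         texture_mode = c("smooth-noise", "uniform", "two-class"),
                         hu_mean = 60, hu_sd = 20,
                         artifact_fraction = 0.15,
                         seed = 1L) {
  texture_mode <- match.arg(texture_mode)
  stopifnot(length(grid_shape) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stopf("spacing must be strictly positive")
  if (n_ln_range[1] < 1L || n_ln_range[2] > 5L || n_ln_range[1] > n_ln_range[2])
    stopf("n_ln_range must be a subset of [1, 5]")
  if (pt_radius_range[1] > pt_radius_range[2] ||
      ln_radius_range[1] > ln_radius_range[2])
    stopf("radius ranges must be non-degenerate or collapsed to a point")
  if (artifact_fraction < 0 || artifact_fraction > 1)
    stopf("artifact_fraction must be in [0, 1]")
  structure(list(
    n_patients = as.integer(n_patients), grid_shape = as.integer(grid_shape),
    spacing = as.numeric(spacing), pt_radius_range = pt_radius_range,
    n_ln_range = as.integer(n_ln_range), ln_radius_range = ln_radius_range,
    ln_spread = ln_spread, texture_mode = texture_mode,
    hu_mean = hu_mean, hu_sd = hu_sd,
    artifact_fraction = artifact_fraction, seed = as.integer(seed)
  ), class = "phantom_spec")
}

## Random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))))
}

## Superellipsoid membership: |x/a|^e + |y/b|^e + |z/c|^e <= 1 in a
## rotated frame centered at `center` (mm).
superellipsoid_mask <- function(grid_shape, spacing, center, semi_axes,
                                exponent, rotation) {
  idx <- as.matrix(expand.grid(
    x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
    z = seq_len(grid_shape[3])))
  pos <- sweep(idx - 1, 2, spacing, `*`)
  rel <- sweep(pos, 2, center) %*% rotation
  u <- abs(sweep(rel, 2, semi_axes, `/`))
  inside <- rowSums(u^exponent) <= 1
  array(inside, dim = grid_shape)
}

## One blob with random shape; returns NULL if it leaves the grid or
## is empty after voxelization.
place_blob <- function(grid_shape, spacing, center, mean_radius) {
  ratios <- exp(stats::runif(3, log(0.7), log(1.4)))
  expo <- stats::runif(1, 1.7, 2.6)
  ## superellipsoid volume = vfac(e) * a*b*c; scale the semi-axes so the
  ## analytic volume equals the sphere of the requested mean radius
  vfac <- 8 * gamma(1 + 1 / expo)^3 / gamma(1 + 3 / expo)
  semi <- mean_radius * ratios / prod(ratios)^(1 / 3) *
    ((4 * pi / 3) / vfac)^(1 / 3)
  ## keep every axis thick enough to survive coarse resampling
  semi <- pmax(semi, min(4.2, mean_radius))
  rot <- random_rotation()
  extent <- (grid_shape - 1) * spacing
  if (any(center - max(semi) < 0) || any(center + max(semi) > extent))
    return(NULL)
  m <- superellipsoid_mask(grid_shape, spacing, center, semi, expo, rot)
  if (!any(m)) NULL else m
}

## ROI texture fill per texture_mode. Noise is generated on the ROI
## bounding box only (cheaper than the full grid, same distribution).
fill_texture <- function(image, mask, mode, hu_mean, hu_sd) {
  n <- sum(mask)
  if (mode == "uniform") { image[mask] <- hu_mean; return(image) }
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(image))
  sub_mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  noise <- box_smooth3(array(stats::rnorm(prod(dim(sub_mask))), dim(sub_mask)))
  v <- noise[sub_mask]
  vals <- if (mode == "smooth-noise") {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(hu_mean, n)
    else hu_mean + (v - mean(v)) / s * hu_sd
  } else {  # two-class
    hu_mean + ifelse(v > stats::median(v), hu_sd, -hu_sd)
  }
  sub_img <- image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_img[sub_mask] <- vals
  image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub_img
  image
}

#' Generate a phantom cohort of image volumes with PT and LN masks
#'
#' Each patient receives one connected primary-tumor (PT) blob and 1--5
#' lymph-node (LN) blobs, all superellipsoids with random axis ratios and
#' rigid rotation, disjoint from one another, filled with soft-tissue-like
#' HU texture. A fraction of patients gets extreme-HU streaks on recorded
#' axial slices, which the preprocessing eligibility rule acts on.
#'
#' @param spec A [phantom_spec()].
#' @return A list of `volume_with_masks` objects: each has `image`
#'   (3D HU array), `pt_mask`, `ln_mask` (binary arrays), `spacing` (mm),
#'   `artifact_slices` (integer axial indices) and `patient_id`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  extent <- (spec$grid_shape - 1) * spec$spacing
  min_extent <- min(extent)
  if (min_extent < 2 * max(spec$pt_radius_range) + 4 * max(spec$spacing) ||
      min_extent < 4 * max(spec$ln_radius_range))
    stopf("grid too small to place the requested blobs: extent %.1f mm", min_extent)
  lapply(seq_len(spec$n_patients), function(pid) {
    pt_r <- stats::runif(1, spec$pt_radius_range[1], spec$pt_radius_range[2])
    n_ln <- if (spec$n_ln_range[1] == spec$n_ln_range[2]) spec$n_ln_range[1]
            else sample(spec$n_ln_range[1]:spec$n_ln_range[2], 1)
    center0 <- extent / 2
    pt_mask <- NULL
    for (try in 1:50) {
      jitter <- stats::rnorm(3, 0, spec$ln_spread / 6)
      pt_mask <- place_blob(spec$grid_shape, spec$spacing, center0 + jitter, pt_r)
      if (!is.null(pt_mask)) break
    }
    if (is.null(pt_mask)) stopf("patient %d: failed to place PT blob", pid)
    occupied <- pt_mask
    ln_mask <- array(FALSE, spec$grid_shape)
    placed <- 0L
    for (j in seq_len(n_ln)) {
      ln_r <- stats::runif(1, spec$ln_radius_range[1], spec$ln_radius_range[2])
      ok <- FALSE
      min_dist <- pt_r + ln_r + 2 * max(spec$spacing)
      for (try in 1:200) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        dist <- max(min_dist,
                    stats::rnorm(1, spec$ln_spread, spec$ln_spread / 5))
        ## shrink toward the feasible shell as retries accumulate
        if (try > 100) dist <- min_dist
        ctr <- center0 + dir * dist
        m <- place_blob(spec$grid_shape, spec$spacing, ctr, ln_r)
        if (is.null(m)) next
        ## keep structures separated by at least one voxel
        dil <- m
        for (r in seq_len(nrow(neighbor_offsets_26())))
          dil <- dil | shift3d(m, neighbor_offsets_26()[r, ], fill = FALSE)
        if (any(dil & occupied)) next
        ln_mask <- ln_mask | m
        occupied <- occupied | dil
        ok <- TRUE
        break
      }
      if (!ok) stopf("patient %d: failed to place LN blob %d of %d (grid too crowded)",
                     pid, j, n_ln)
      placed <- placed + 1L
    }
    image <- array(-1000, spec$grid_shape)  # air background
    roi <- pt_mask | ln_mask
    image <- fill_texture(image, roi, spec$texture_mode, spec$hu_mean, spec$hu_sd)
    artifact_slices <- integer(0)
    if (stats::runif(1) < spec$artifact_fraction) {
      z_roi <- which(apply(roi, 3, any))
      n_bad <- min(length(z_roi), sample(1:3, 1))
      artifact_slices <- sort(sample(z_roi, n_bad))
      for (z in artifact_slices) {
        streak <- matrix(stats::runif(prod(spec$grid_shape[1:2])) < 0.5,
                         spec$grid_shape[1])
        sl <- image[, , z]
        sl[streak] <- 3000; sl[!streak] <- -1000
        image[, , z] <- sl
      }
    }
    structure(list(
      patient_id = sprintf("P%03d", pid), image = image,
      pt_mask = pt_mask, ln_mask = ln_mask,
      spacing = spec$spacing, artifact_slices = artifact_slices,
      eligible = NA), class = "volume_with_masks")
  })
}

#' Ground truth for outcome simulation
#'
#' @param planted_features Named numeric vector of Cox log-hazard-ratio
#'   coefficients on (z-scored) feature columns driving local control (LC).
#' @param regional_features Named numeric vector of coefficients driving
#'   the regional-failure component of loco-regional control (LRC).
#' @param baseline_hazard Baseline LC event rate per month.
#' @param regional_hazard Baseline regional event rate per month.
#' @param censor_rate Independent exponential censoring rate per month.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(planted_features = c(),
                         regional_features = c(),
                         baseline_hazard = 0.02,
                         regional_hazard = 0.012,
                         censor_rate = 0.015) {
  if (baseline_hazard <= 0 || regional_hazard <= 0)
    stopf("hazard rates must be > 0")
  if (censor_rate < 0) stopf("censor_rate must be >= 0")
  if (length(planted_features) && any(!is.finite(planted_features)))
    stopf("planted coefficients must be finite")
  structure(list(planted_features = planted_features,
                 regional_features = regional_features,
                 baseline_hazard = baseline_hazard,
                 regional_hazard = regional_hazard,
                 censor_rate = censor_rate), class = "ground_truth")
}

z_score_cols <- function(X) {
  s <- apply(X, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  scale(X, center = TRUE, scale = s)
}

#' Simulate linked LC / LRC survival outcomes from a feature matrix
#'
#' Local-control (LC) failure times are exponential with hazard
#' `baseline_hazard * exp(lp)` where `lp` is the linear predictor of the
#' planted features (z-scored). Regional failures are an independent
#' exponential clock driven by `regional_features`; the loco-regional
#' (LRC) failure time is the earlier of the two, so every LC failure is
#' also an LRC failure. Censoring is independent exponential and shared
#' between the two endpoints.
#'
#' @param features Numeric matrix (patients x features) with column names.
#' @param truth A [ground_truth()].
#' @param seed Integer seed.
#' @return A data.frame (`survival_table`): `patient_id`, `lc_time`,
#'   `lc_event`, `lrc_time`, `lrc_event`, `n_stage` (ordinal 1--5).
#' @export
simulate_outcomes <- function(features, truth, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- nrow(features)
  lp_of <- function(coefs) {
    if (!length(coefs)) return(rep(0, n))
    missing <- setdiff(names(coefs), colnames(features))
    if (length(missing))
      stopf("planted feature(s) not present in the feature matrix: %s",
            paste(missing, collapse = ", "))
    Z <- z_score_cols(features[, names(coefs), drop = FALSE])
    as.numeric(Z %*% coefs)
  }
  lp_lc <- lp_of(truth$planted_features)
  lp_rg <- lp_of(truth$regional_features)
  set.seed(seed)
  t_lc <- stats::rexp(n, truth$baseline_hazard * exp(lp_lc))
  t_rg <- stats::rexp(n, truth$regional_hazard * exp(lp_rg))
  t_lrc <- pmin(t_lc, t_rg)
  t_cens <- if (truth$censor_rate > 0) stats::rexp(n, truth$censor_rate)
            else rep(Inf, n)
  out <- data.frame(
    patient_id = if (!is.null(rownames(features))) rownames(features)
                 else sprintf("P%03d", seq_len(n)),
    lc_time = pmin(t_lc, t_cens), lc_event = as.integer(t_lc <= t_cens),
    lrc_time = pmin(t_lrc, t_cens), lrc_event = as.integer(t_lrc <= t_cens),
    n_stage = sample(1:5, n, replace = TRUE,
                     prob = c(0.08, 0.03, 0.5, 0.32, 0.07)),
    stringsAsFactors = FALSE)
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Simulate a feature-level cohort with planted prognostic structure
#'
#' Draws PT, LN and LNPT feature matrices directly, without image
#' synthesis, for fast selection- and model-recovery studies where the
#' imaging stage is not under test. Radiomic panels are heavily
#' redundant, so each group consists of a few mutually independent
#' candidate columns (the first `n_indep`; these are the ones outcomes
#' can be planted on) plus redundancy blocks of near-duplicate features
#' (block base signal plus small jitter), which reproduces both the low
#' PCA dimension and the high Spearman redundancy of real panels.
#'
#' @param n Number of patients.
#' @param n_pt,n_ln,n_lnpt Number of features per group.
#' @param n_indep Independent candidate columns per group.
#' @param n_blocks Redundancy blocks per group.
#' @param jitter_sd Within-block perturbation SD (base signals are
#'   standard normal).
#' @param seed Integer seed.
#' @return List with matrices `pt`, `ln`, `lnpt` (named columns
#'   `pt_f001`, ...).
#' @export
simulate_feature_cohort <- function(n = 150L, n_pt = 30L, n_ln = 30L,
                                    n_lnpt = 14L, n_indep = 2L,
                                    n_blocks = 3L, jitter_sd = 0.15,
                                    seed = 1L) {
  set.seed(seed)
  draw <- function(p, prefix) {
    stopifnot(p > n_indep)
    X <- matrix(0, n, p)
    X[, seq_len(n_indep)] <- stats::rnorm(n * n_indep)
    base <- matrix(stats::rnorm(n * n_blocks), n)
    blk <- rep_len(seq_len(n_blocks), p - n_indep)
    for (j in seq_len(p - n_indep))
      X[, n_indep + j] <- base[, blk[j]] + stats::rnorm(n, 0, jitter_sd)
    colnames(X) <- sprintf("%s_f%03d", prefix, seq_len(p))
    rownames(X) <- sprintf("P%03d", seq_len(n))
    X
  }
  list(pt = draw(n_pt, "pt"), ln = draw(n_ln, "ln"), lnpt = draw(n_lnpt, "lnpt"))
}

#' Write a phantom cohort to disk as NIfTI volumes plus a clinical CSV
#'
#' @param cohort List from [generate_cohort()].
#' @param outcomes Optional `survival_table` from [simulate_outcomes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `<id>_image.nii.gz`, `<id>_pt.nii.gz`,
#'   `<id>_ln.nii.gz` per patient and `clinical.csv` if outcomes given.
#' @export
write_cohort <- function(cohort, outcomes = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in cohort) {
    pd <- v$spacing
    wr <- function(arr, suffix) {
      img <- RNifti::asNifti(arr * 1.0, reference = NULL)
      RNifti::pixdim(img) <- pd
      RNifti::writeNifti(img, file.path(dir, paste0(v$patient_id, suffix)))
    }
    wr(v$image, "_image.nii.gz")
    wr(v$pt_mask, "_pt.nii.gz")
    wr(v$ln_mask, "_ln.nii.gz")
    meta <- list(patient_id = v$patient_id,
                 artifact_slices = as.integer(v$artifact_slices),
                 spacing = v$spacing)
    jsonlite::write_json(meta, file.path(dir, paste0(v$patient_id, "_meta.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(outcomes))
    utils::write.csv(outcomes, file.path(dir, "clinical.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the NIfTI and metadata files.
#' @return List of `volume_with_masks`.
#' @export
read_cohort <- function(dir) {
  metas <- sort(list.files(dir, "_meta\\.json$", full.names = TRUE))
  lapply(metas, function(mf) {
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    id <- meta$patient_id
    rd <- function(suffix) {
      img <- RNifti::readNifti(file.path(dir, paste0(id, suffix)))
      array(as.numeric(img), dim = dim(img))
    }
    structure(list(
      patient_id = id, image = rd("_image.nii.gz"),
      pt_mask = rd("_pt.nii.gz") > 0.5, ln_mask = rd("_ln.nii.gz") > 0.5,
      spacing = as.numeric(meta$spacing),
      artifact_slices = as.integer(meta$artifact_slices),
      eligible = NA), class = "volume_with_masks")
  })
}
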