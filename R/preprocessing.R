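## ROI preparation: artifact-slice handling with the 50% eligibility rule,
## isotropic resampling, soft-tissue HU windowing, LN merging.

#' Preprocessing configuration
#'
#' @param target_spacing Isotropic output voxel size in mm. The default
#'   3.3 mm matches the coarsest voxel dimension typically encountered in
#'   head-and-neck planning CT series.
#' @param hu_window Closed HU interval retained for intensity and texture
#'   analysis; the default \[-20, 180\] restricts analysis to soft tissue.
#' @param artifact_volume_limit Patients whose ROI has at least this
#'   fraction of its volume on artifact slices are ineligible (strict
#'   "less than" rule).
#' @param mask_threshold Re-binarization threshold after trilinear mask
#'   resampling.
#' @param eligibility_scope `"combined"` evaluates the artifact fraction
#'   on PT union LN; `"per-roi"` requires both ROIs to pass separately.
#' @param window_before_resample If `TRUE`, HU windowing is applied before
#'   resampling instead of after.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = 3.3,
                              hu_window = c(-20, 180),
                              artifact_volume_limit = 0.5,
                              mask_threshold = 0.5,
                              eligibility_scope = c("combined", "per-roi"),
                              window_before_resample = FALSE) {
  eligibility_scope <- match.arg(eligibility_scope)
  if (hu_window[1] >= hu_window[2]) stopf("hu_window lower bound must be < upper")
  if (artifact_volume_limit <= 0 || artifact_volume_limit > 1)
    stopf("artifact_volume_limit must be in (0, 1]")
  if (target_spacing <= 0) stopf("target_spacing must be > 0")
  structure(list(target_spacing = target_spacing, hu_window = hu_window,
                 artifact_volume_limit = artifact_volume_limit,
                 mask_threshold = mask_threshold,
                 eligibility_scope = eligibility_scope,
                 window_before_resample = window_before_resample),
            class = "preprocess_config")
}

#' Artifact-volume eligibility check
#'
#' A patient is eligible when the fraction of ROI volume lying on
#' artifact-affected axial slices is strictly below the configured limit
#' (default 50%). Evaluated on the original masks, before any slice
#' removal.
#'
#' @param v A `volume_with_masks`.
#' @param cfg A [preprocess_config()].
#' @return Logical scalar; attribute `artifact_fraction` carries the
#'   computed fraction.
#' @export
check_eligibility <- function(v, cfg = preprocess_config()) {
  roi_of <- function(m) {
    tot <- sum(m)
    if (tot == 0) stopf("empty ROI: eligibility undefined for patient %s",
                        v$patient_id %||% "<unknown>")
    bad <- if (length(v$artifact_slices))
      sum(m[, , v$artifact_slices, drop = FALSE]) else 0
    bad / tot
  }
  frac <- if (cfg$eligibility_scope == "combined") {
    roi_of(v$pt_mask | v$ln_mask)
  } else {
    max(roi_of(v$pt_mask), roi_of(v$ln_mask))
  }
  structure(frac < cfg$artifact_volume_limit, artifact_fraction = frac)
}

#' Remove ROI contours from artifact-affected slices
#'
#' Zeroes PT and LN mask voxels on the recorded artifact slices; the image
#' itself is untouched. An empty artifact set is a no-op.
#'
#' @param v A `volume_with_masks`.
#' @return The modified copy.
#' @export
remove_artifact_slices <- function(v) {
  if (!length(v$artifact_slices)) return(v)
  bad <- v$artifact_slices
  if (any(bad < 1L | bad > dim(v$pt_mask)[3]))
    stopf("artifact slice index out of range")
  v$pt_mask[, , bad] <- FALSE
  v$ln_mask[, , bad] <- FALSE
  v
}

## Trilinear interpolation of a 3D array at fractional 0-based voxel
## coordinates (matrix n x 3), with edge clamping.
trilinear_at <- function(a, pts) {
  d <- dim(a)
  p <- pmin(pmax(pts, 0), matrix(rep(d - 1L, each = nrow(pts)), ncol = 3))
  i0 <- floor(p); fr <- p - i0
  i0 <- pmin(i0, matrix(rep(d - 2L, each = nrow(pts)), ncol = 3))
  i0[i0 < 0] <- 0
  fr <- p - i0
  lin <- function(dx, dy, dz)
    a[cbind(i0[, 1] + 1L + dx, i0[, 2] + 1L + dy, i0[, 3] + 1L + dz)]
  w <- function(f, d1) if (d1 == 1) f else 1 - f
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    out <- out + lin(dx, dy, dz) *
      w(fr[, 1], dx) * w(fr[, 2], dy) * w(fr[, 3], dz)
  out
}

#' Resample a volume and its masks to isotropic voxels
#'
#' Trilinear interpolation for the image; trilinear plus threshold
#' re-binarization for the masks. Voxel centers sit at
#' `index * spacing` (0-based) with a shared origin, so the physical
#' extent is preserved to within one voxel per axis.
#'
#' @param v A `volume_with_masks`.
#' @param cfg A [preprocess_config()].
#' @return The resampled `volume_with_masks` (spacing updated; artifact
#'   slice bookkeeping dropped, since it applies to the original grid).
#' @export
resample_volume <- function(v, cfg = preprocess_config()) {
  t <- cfg$target_spacing
  d_in <- dim(v$image)
  extent <- (d_in - 1) * v$spacing
  d_out <- pmax(1L, as.integer(floor(extent / t)) + 1L)
  if (any(d_out < 1L)) stopf("resampling produced a zero-size grid")
  g <- as.matrix(expand.grid(x = seq_len(d_out[1]) - 1L,
                             y = seq_len(d_out[2]) - 1L,
                             z = seq_len(d_out[3]) - 1L))
  pts <- sweep(sweep(g, 2, rep(t, 3), `*`), 2, v$spacing, `/`)
  res <- function(a, binar = FALSE) {
    vals <- trilinear_at(a * 1.0, pts)
    out <- array(vals, dim = d_out)
    if (binar) out >= cfg$mask_threshold else out
  }
  v$image <- res(v$image)
  v$pt_mask <- res(v$pt_mask, binar = TRUE)
  v$ln_mask <- res(v$ln_mask, binar = TRUE)
  if (!is.null(v$valid_mask)) v$valid_mask <- res(v$valid_mask, binar = TRUE)
  v$spacing <- rep(t, 3)
  v$artifact_slices <- integer(0)
  v
}

#' Mark ROI voxels outside the soft-tissue HU window as invalid
#'
#' Voxels outside the closed interval `hu_window` are excluded from
#' intensity and texture analysis (they are not clamped); shape features
#' keep using the full mask. Adds a `valid_mask` to the volume.
#'
#' @param v A `volume_with_masks`.
#' @param cfg A [preprocess_config()].
#' @return The volume with `valid_mask` set.
#' @export
window_hu <- function(v, cfg = preprocess_config()) {
  w <- cfg$hu_window
  v$valid_mask <- v$image >= w[1] & v$image <= w[2]
  v
}

#' Label connected lymph-node components and merge them into one ROI
#'
#' Components are labeled under 26-connectivity; the merged ROI is the
#' union of all components, while the per-component labels are retained
#' for the spatial LN-distribution features.
#'
#' @param v A `volume_with_masks`.
#' @return The volume with `ln_labels` (integer array, 0 = background)
#'   and `n_ln_components` added; `ln_mask` is the union.
#' @export
merge_ln <- function(v) {
  v$ln_labels <- label_components_26(v$ln_mask)
  v$n_ln_components <- max(v$ln_labels)
  v
}

#' 26-connected component labeling of a binary 3D mask
#'
#' Iterative minimum-label propagation; labels are renumbered 1..K in
#' order of first (column-major) occurrence.
#'
#' @param mask Binary 3D array.
#' @return Integer array of the same shape, 0 outside the mask.
#' @export
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  offs <- neighbor_offsets_26()
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offs))) {
      s <- shift3d(lab, offs[r, ], fill = 0)
      upd <- mask & s > 0 & (s < lab)
      if (any(upd)) { lab[upd] <- s[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  u <- unique(lab[lab > 0])
  lab2 <- array(0L, d)
  lab2[lab > 0] <- match(lab[lab > 0], u)
  lab2
}

#' Run the full preprocessing chain on one patient
#'
#' Eligibility check (on original masks), artifact-slice contour removal,
#' isotropic resampling, HU windowing and LN merging, in the configured
#' order.
#'
#' @param v A `volume_with_masks`.
#' @param cfg A [preprocess_config()].
#' @return The preprocessed volume; `eligible` and `artifact_fraction`
#'   fields are set. Ineligible patients are returned unprocessed with
#'   `eligible = FALSE`.
#' @export
preprocess_patient <- function(v, cfg = preprocess_config()) {
  el <- check_eligibility(v, cfg)
  v$eligible <- as.logical(el)
  v$artifact_fraction <- attr(el, "artifact_fraction")
  if (!v$eligible) return(v)
  v <- remove_artifact_slices(v)
  if (cfg$window_before_resample) {
    v <- window_hu(v, cfg)
    v <- resample_volume(v, cfg)
  } else {
    v <- resample_volume(v, cfg)
    v <- window_hu(v, cfg)
  }
  merge_ln(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
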