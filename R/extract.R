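## Feature manifest and the per-ROI / per-patient extraction entry points.

#' The 285-feature manifest
#'
#' Defines the panel: 18 shape + 17 intensity + 72 texture features on
#' the original image, plus the 17 + 72 = 89 intensity and texture
#' features recomputed on the LLL and HHH wavelet subbands (178), for a
#' total of 285 per ROI. Wavelet subbands are re-discretized with a fixed
#' bin count over their own ROI range.
#'
#' @param disc A [discretization()] for the original image.
#' @param wavelet_disc A [discretization()] for the subbands.
#' @return An object of class `feature_manifest` with the name rosters.
#' @export
feature_manifest <- function(disc = discretization(),
                             wavelet_disc = discretization(
                               mode = "fixed-bin-count", n_bins = 40L)) {
  shape <- names(extract_shape(array(TRUE, c(2, 2, 2)), c(1, 1, 1)))
  tiny <- array(c(1, 2), c(2, 2, 2))
  inten <- names(extract_intensity(tiny, array(TRUE, c(2, 2, 2)), disc))
  lv <- discretize(tiny, array(TRUE, c(2, 2, 2)), disc)
  tex <- names(extract_texture(lv))
  subbands <- c("LLL", "HHH")
  wav <- as.character(sapply(subbands, function(sb)
    paste0(c(inten, tex), "_", sb)))
  structure(list(shape_names = shape, intensity_names = inten,
                 texture_names = tex, wavelet_names = wav,
                 subbands = subbands, disc = disc,
                 wavelet_disc = wavelet_disc,
                 all_names = c(shape, inten, tex, wav)),
            class = "feature_manifest")
}

#' Extract the full 285-feature vector for one ROI
#'
#' @param image 3D HU grid (preprocessed).
#' @param mask Binary ROI mask (full mask; used for shape).
#' @param valid_mask Binary grid of in-window voxels (intensity/texture);
#'   defaults to `mask`.
#' @param spacing mm per axis.
#' @param manifest A [feature_manifest()].
#' @return Named numeric vector of length 285, ordered as the manifest.
#' @export
extract_roi <- function(image, mask, valid_mask = mask, spacing,
                        manifest = feature_manifest()) {
  if (!any(mask)) stopf("empty ROI mask")
  vm <- valid_mask & mask
  if (sum(vm) < 2L)
    stopf("ROI has fewer than 2 in-window voxels")
  out <- c(extract_shape(mask, spacing, image = image),
           extract_intensity(image, vm, manifest$disc),
           extract_texture(discretize(image, vm, manifest$disc)))
  wm <- wavelet_maps(image, vm)
  for (sb in manifest$subbands) {
    sub <- wm[[sb]]
    fs <- c(extract_intensity(sub, vm, manifest$wavelet_disc),
            extract_texture(discretize(sub, vm, manifest$wavelet_disc)))
    names(fs) <- paste0(names(fs), "_", sb)
    out <- c(out, fs)
  }
  stopifnot(identical(names(out), manifest$all_names))
  out
}

#' Extract PT and LN feature vectors for one preprocessed patient
#'
#' @param v A preprocessed `volume_with_masks` (after
#'   [preprocess_patient()]).
#' @param manifest A [feature_manifest()].
#' @return List with numeric vectors `pt` and `ln` (285 entries each).
#' @export
extract_all <- function(v, manifest = feature_manifest()) {
  if (is.null(v$valid_mask)) v <- window_hu(v)
  list(pt = extract_roi(v$image, v$pt_mask, v$valid_mask, v$spacing, manifest),
       ln = extract_roi(v$image, v$ln_mask, v$valid_mask, v$spacing, manifest))
}

#' Build the cohort feature matrices (PT, LN, LNPT) from preprocessed
#' patients
#'
#' @param cohort List of preprocessed `volume_with_masks`; ineligible
#'   patients are skipped.
#' @param manifest A [feature_manifest()].
#' @return List of matrices `pt`, `ln` (patients x 285) and `lnpt`
#'   (patients x 14), with patient ids as row names.
#' @export
extract_cohort <- function(cohort, manifest = feature_manifest()) {
  keep <- Filter(function(v) isTRUE(v$eligible) || is.na(v$eligible), cohort)
  ids <- vapply(keep, function(v) v$patient_id, "")
  rows <- lapply(keep, function(v) {
    fv <- extract_all(v, manifest)
    ln14 <- extract_lnpt(structure_set_from_volume(v))
    list(pt = fv$pt, ln = fv$ln, lnpt = ln14)
  })
  bind <- function(part) {
    m <- do.call(rbind, lapply(rows, `[[`, part))
    rownames(m) <- ids
    m
  }
  list(pt = bind("pt"), ln = bind("ln"), lnpt = bind("lnpt"))
}
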