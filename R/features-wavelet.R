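## One-level 3D stationary (undecimated) Haar wavelet transform on the
## ROI bounding box; only the all-low-pass (LLL) and all-high-pass (HHH)
## subbands are analyzed downstream.

## 1D stationary Haar step along an axis with edge replication:
## lo[i] = (a[i] + a[i+1]) / sqrt(2), hi[i] = (a[i] - a[i+1]) / sqrt(2).
haar_axis <- function(a, axis, high = FALSE) {
  d <- dim(a)
  idx <- seq_len(d[axis])
  nxt <- pmin(idx + 1L, d[axis])
  pick <- function(arr, ix) {
    switch(axis,
           arr[ix, , , drop = FALSE],
           arr[, ix, , drop = FALSE],
           arr[, , ix, drop = FALSE])
  }
  b <- pick(a, nxt)
  if (high) (a - b) / sqrt(2) else (a + b) / sqrt(2)
}

#' LLL and HHH Haar subbands of the ROI bounding box
#'
#' Applies the separable stationary Haar filters along each axis (edge
#' replication at the boundary; low-pass DC gain `sqrt(2)` per axis, so a
#' constant `c` maps to `2 sqrt(2) c` in LLL and to 0 in HHH). The
#' subbands are returned on the original lattice, with values outside the
#' bounding box left untouched.
#'
#' @param image 3D numeric grid.
#' @param valid_mask Binary grid; the transform runs on the mask's
#'   bounding box, which must span at least 2 voxels per axis.
#' @return List with 3D arrays `LLL` and `HHH`.
#' @export
wavelet_maps <- function(image, valid_mask) {
  if (!any(valid_mask)) stopf("empty ROI: wavelet maps undefined")
  idx <- which(valid_mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  span <- hi - lo + 1L
  ax_names <- c("x", "y", "z")
  if (any(span < 2L))
    stopf("ROI thinner than the wavelet filter support along axis %s",
          paste(ax_names[span < 2L], collapse = ", "))
  sub <- image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  lll <- sub; hhh <- sub
  for (ax in 1:3) {
    lll <- haar_axis(lll, ax, high = FALSE)
    hhh <- haar_axis(hhh, ax, high = TRUE)
  }
  outL <- image; outH <- image
  outL[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- lll
  outH[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- hhh
  list(LLL = outL, HHH = outH)
}
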