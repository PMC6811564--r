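## First-order intensity statistics and grey-level discretization.

#' Discretization settings
#'
#' Fixed-bin-size binning anchored at the HU window lower bound is used
#' for the original image (default 5 HU bins over \[-20, 180\], i.e. at
#' most 40 bins); wavelet subbands are re-binned with a fixed bin count
#' over their own ROI range.
#'
#' @param mode `"fixed-bin-size"` or `"fixed-bin-count"`.
#' @param bin_width Bin width (HU) for fixed-bin-size.
#' @param n_bins Bin count for fixed-bin-count.
#' @param anchor Lower edge of the first bin for fixed-bin-size.
#' @param upper Upper edge of the binned range for fixed-bin-size (values
#'   at the top edge are assigned to the last bin).
#' @return An object of class `discretization`.
#' @export
discretization <- function(mode = c("fixed-bin-size", "fixed-bin-count"),
                           bin_width = 5, n_bins = 40L,
                           anchor = -20, upper = 180) {
  mode <- match.arg(mode)
  structure(list(mode = mode, bin_width = bin_width,
                 n_bins = as.integer(n_bins), anchor = anchor, upper = upper),
            class = "discretization")
}

#' Discretize ROI intensities into integer grey levels
#'
#' Fixed-bin-size: `level = floor((x - anchor) / bin_width) + 1`, with the
#' top window edge assigned to the last bin. Fixed-bin-count: `n_bins`
#' equal bins over the observed ROI range (a constant ROI maps to
#' level 1).
#'
#' @param image 3D numeric grid.
#' @param valid_mask Binary grid of voxels to discretize.
#' @param disc A [discretization()].
#' @return Integer 3D grid; `NA` outside `valid_mask`. Attribute
#'   `n_levels` gives the nominal level count.
#' @export
discretize <- function(image, valid_mask, disc = discretization()) {
  out <- array(NA_integer_, dim(image))
  x <- image[valid_mask]
  if (!length(x)) return(structure(out, n_levels = 0L))
  if (disc$mode == "fixed-bin-size") {
    nb <- as.integer(ceiling((disc$upper - disc$anchor) / disc$bin_width))
    lv <- pmin(floor((x - disc$anchor) / disc$bin_width) + 1L, nb)
    lv <- pmax(lv, 1L)
  } else {
    nb <- disc$n_bins
    rng <- range(x)
    if (rng[1] == rng[2]) lv <- rep(1L, length(x))
    else lv <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * nb) + 1L, nb)
  }
  out[valid_mask] <- as.integer(lv)
  structure(out, n_levels = nb)
}

#' Extract the 17 first-order intensity features of a ROI
#'
#' Statistics are computed over the in-window (valid) ROI voxels; moments
#' use the population convention, kurtosis is excess kurtosis, and the
#' histogram entropy uses the same grey-level binning as the texture
#' features.
#'
#' @param image 3D numeric grid.
#' @param valid_mask Binary grid of included voxels (>= 2 required).
#' @param disc A [discretization()] for the histogram entropy.
#' @return Named numeric vector of length 17.
#' @export
extract_intensity <- function(image, valid_mask, disc = discretization()) {
  x <- image[valid_mask]
  if (length(x) < 2L)
    stopf("fewer than 2 valid ROI voxels: intensity features undefined")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sdv <- sqrt(m2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else 0
  q <- stats::quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE,
                       type = 7)
  sub <- x[x >= q[1] & x <= q[5]]
  lv <- discretize(image, valid_mask, disc)
  p <- tabulate(lv[valid_mask])
  p <- p[p > 0] / n
  c(intensity_mean = mu,
    intensity_variance = m2,
    intensity_sd = sdv,
    intensity_skewness = skew,
    intensity_kurtosis = kurt,
    intensity_median = q[3],
    intensity_min = min(x),
    intensity_max = max(x),
    intensity_range = max(x) - min(x),
    intensity_p10 = q[1],
    intensity_p90 = q[5],
    intensity_iqr = q[4] - q[2],
    intensity_mad = mean(abs(x - mu)),
    intensity_robust_mad = mean(abs(sub - mean(sub))),
    intensity_energy = sum(x^2),
    intensity_rms = sqrt(mean(x^2)),
    intensity_hist_entropy = -sum(p * log2(p)))
}
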