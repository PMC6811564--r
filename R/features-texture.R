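## 3D texture matrices (GLCM, GLRLM, GLSZM, NGTDM, NGLDM) and their
## 72 scalar features. Grey levels are 1..Ng integers, NA outside the
## valid ROI. Conventions: 13 symmetric direction offsets at Chebyshev
## distance 1; GLCM probability matrices are averaged over directions
## before feature computation; GLRLM counts are merged over directions;
## GLSZM zones use 26-connectivity; NGTDM/NGLDM use the 26-neighbourhood.

#' Direction-averaged symmetric grey-level co-occurrence matrix
#'
#' @param levels Integer grid (NA = invalid).
#' @param n_levels Number of grey levels Ng.
#' @return Ng x Ng probability matrix (averaged over the directions that
#'   contain at least one voxel pair).
#' @export
glcm_matrix <- function(levels, n_levels) {
  dirs <- direction_offsets_13()
  acc <- matrix(0, n_levels, n_levels)
  used <- 0L
  for (r in seq_len(nrow(dirs))) {
    s <- shift3d(levels, dirs[r, ], fill = NA)
    ok <- !is.na(levels) & !is.na(s)
    if (!any(ok)) next
    a <- levels[ok]; b <- s[ok]
    cnt <- matrix(tabulate((a - 1L) * n_levels + b, nbins = n_levels^2),
                  n_levels, byrow = TRUE)
    cnt <- cnt + t(cnt)
    acc <- acc + cnt / sum(cnt)
    used <- used + 1L
  }
  if (used == 0L) return(acc)
  acc / used
}

#' GLCM features (25)
#'
#' @param P Ng x Ng probability matrix from [glcm_matrix()].
#' @return Named numeric vector of length 25.
#' @export
glcm_features <- function(P) {
  eps0 <- function(x) ifelse(x > 0, x, 1)  # for logs of zero-prob cells
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  tot <- sum(P)
  if (tot == 0) P1 <- P else P1 <- P / tot
  px <- rowSums(P1)
  mu <- sum(i * P1)
  sig2 <- sum((i - mu)^2 * P1)
  dif <- abs(i - j)
  pd <- tapply(P1, dif, sum)               # p_{|i-j|}, names 0..Ng-1
  kd <- as.numeric(names(pd))
  ps <- tapply(P1, i + j, sum)             # p_{i+j}, names 2..2Ng
  ks <- as.numeric(names(ps))
  d_avg <- sum(kd * pd)
  s_avg <- sum(ks * ps)
  Hxy <- -sum(P1 * log2(eps0(P1)))
  Hx <- -sum(px * log2(eps0(px)))
  pxj <- px[i] * px[j]
  Hxy1 <- -sum(P1 * log2(eps0(pxj)))
  Hxy2 <- -sum(pxj * log2(eps0(pxj)))
  corr <- if (sig2 > 0) (sum(i * j * P1) - mu^2) / sig2 else 0
  ic1 <- if (Hx > 0) (Hxy - Hxy1) / Hx else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (Hxy2 - Hxy))))
  offd <- dif > 0
  c(glcm_joint_maximum = max(P1),
    glcm_joint_average = mu,
    glcm_joint_variance = sig2,
    glcm_entropy = Hxy,
    glcm_difference_average = d_avg,
    glcm_difference_variance = sum((kd - d_avg)^2 * pd),
    glcm_difference_entropy = -sum(pd * log2(eps0(pd))),
    glcm_sum_average = s_avg,
    glcm_sum_variance = sum((ks - s_avg)^2 * ps),
    glcm_sum_entropy = -sum(ps * log2(eps0(ps))),
    glcm_angular_second_moment = sum(P1^2),
    glcm_contrast = sum((i - j)^2 * P1),
    glcm_dissimilarity = sum(dif * P1),
    glcm_inverse_difference = sum(P1 / (1 + dif)),
    glcm_inverse_difference_normalized = sum(P1 / (1 + dif / ng)),
    glcm_inverse_difference_moment = sum(P1 / (1 + dif^2)),
    glcm_inverse_difference_moment_normalized = sum(P1 / (1 + dif^2 / ng^2)),
    glcm_inverse_variance = sum(P1[offd] / dif[offd]^2),
    glcm_correlation = corr,
    glcm_autocorrelation = sum(i * j * P1),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * P1),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * P1),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * P1),
    glcm_information_correlation_1 = ic1,
    glcm_information_correlation_2 = ic2)
}

#' Grey-level run-length matrix, merged over the 13 directions
#'
#' @param levels Integer grid (NA = invalid).
#' @param n_levels Ng.
#' @return Ng x Lmax count matrix; attribute `n_dirs` = 13.
#' @export
glrlm_matrix <- function(levels, n_levels) {
  dirs <- direction_offsets_13()
  d <- dim(levels)
  maxlen <- max(d)
  counts <- matrix(0, n_levels, maxlen)
  valid <- !is.na(levels)
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    prev <- shift3d(levels, off, fill = NA)       # value at x - off
    nxt_same_init <- NULL
    is_start <- valid & (is.na(prev) | prev != levels)
    ## forward run length: rl[x] = 1 + rl[x + off] if same level
    same_fwd <- {
      nx <- shift3d(levels, -off, fill = NA)       # value at x + off
      valid & !is.na(nx) & nx == levels
    }
    rl <- array(1, d); rl[!valid] <- 0
    repeat {
      nb <- shift3d(rl, -off, fill = 0)
      new <- ifelse(same_fwd, 1 + nb, ifelse(valid, 1, 0))
      if (identical(new, rl)) break
      rl <- new
    }
    lv <- levels[is_start]; ln <- rl[is_start]
    if (!length(lv)) next
    tb <- tabulate((lv - 1L) * maxlen + ln, nbins = n_levels * maxlen)
    counts <- counts + matrix(tb, n_levels, maxlen, byrow = TRUE)
  }
  structure(counts, n_dirs = nrow(dirs))
}

## Shared run-length / zone-size feature kernel: R is a level x size
## count matrix; n_vox the number of ROI voxels entering the counts
## (per direction for runs).
rl_features <- function(R, n_vox, prefix, size_name) {
  Ns <- sum(R)
  if (Ns == 0) R1 <- R else R1 <- R / Ns
  i <- row(R); s <- col(R)
  ri <- rowSums(R); rj <- colSums(R)
  mu_i <- sum(i * R1); mu_s <- sum(s * R1)
  p <- R1[R1 > 0]
  out <- c(
    sum(rj / (seq_along(rj))^2) / Ns,        # small emphasis
    sum(rj * (seq_along(rj))^2) / Ns,        # large emphasis
    sum(ri / (seq_along(ri))^2) / Ns,        # low grey level
    sum(ri * (seq_along(ri))^2) / Ns,        # high grey level
    sum(R / (i^2 * s^2)) / Ns,
    sum(R * i^2 / s^2) / Ns,
    sum(R * s^2 / i^2) / Ns,
    sum(R * i^2 * s^2) / Ns,
    sum(ri^2) / Ns,                          # grey level non-uniformity
    sum(ri^2) / Ns^2,
    sum(rj^2) / Ns,                          # size non-uniformity
    sum(rj^2) / Ns^2,
    Ns / n_vox,                              # percentage
    sum((i - mu_i)^2 * R1),
    sum((s - mu_s)^2 * R1),
    -sum(p * log2(p)))
  names(out) <- paste0(prefix, c(
    paste0("short_", size_name, "_emphasis"),
    paste0("long_", size_name, "_emphasis"),
    "low_grey_level_emphasis", "high_grey_level_emphasis",
    paste0("short_", size_name, "_low_grey_level_emphasis"),
    paste0("short_", size_name, "_high_grey_level_emphasis"),
    paste0("long_", size_name, "_low_grey_level_emphasis"),
    paste0("long_", size_name, "_high_grey_level_emphasis"),
    "grey_level_nonuniformity", "grey_level_nonuniformity_normalized",
    paste0(size_name, "_nonuniformity"),
    paste0(size_name, "_nonuniformity_normalized"),
    paste0(size_name, "_percentage"),
    "grey_level_variance",
    paste0(size_name, "_variance"),
    paste0(size_name, "_entropy")))
  out
}

#' GLRLM features (16)
#' @param R Count matrix from [glrlm_matrix()].
#' @param n_vox ROI voxel count.
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(R, n_vox) {
  nd <- attr(R, "n_dirs") %||% 13L
  out <- rl_features(R, n_vox * nd, "glrlm_", "run")
  ## fix naming: run emphasis uses run length terminology
  names(out) <- sub("glrlm_short_run_", "glrlm_short_run_", names(out))
  out
}

#' Label connected equal-level zones (26-connectivity)
#' @noRd
label_zones_26 <- function(levels) {
  d <- dim(levels)
  valid <- !is.na(levels)
  lab <- array(0, d)
  lab[valid] <- seq_len(sum(valid))
  offs <- neighbor_offsets_26()
  lv <- levels
  lv[!valid] <- -1L
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offs))) {
      s <- shift3d(lab, offs[r, ], fill = 0)
      sl <- shift3d(lv, offs[r, ], fill = -2L)
      upd <- valid & s > 0 & sl == lv & s < lab
      if (any(upd)) { lab[upd] <- s[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

#' Grey-level size-zone matrix (26-connected zones)
#'
#' @param levels Integer grid (NA = invalid).
#' @param n_levels Ng.
#' @return Ng x Smax count matrix.
#' @export
glszm_matrix <- function(levels, n_levels) {
  lab <- label_zones_26(levels)
  ok <- lab > 0
  if (!any(ok)) return(matrix(0, n_levels, 1))
  zl <- tapply(levels[ok], lab[ok], function(x) x[1])
  zs <- tapply(lab[ok], lab[ok], length)
  smax <- max(zs)
  counts <- matrix(0, n_levels, smax)
  for (q in seq_along(zs))
    counts[zl[q], zs[q]] <- counts[zl[q], zs[q]] + 1
  counts
}

#' GLSZM features (16)
#' @param S Count matrix from [glszm_matrix()].
#' @param n_vox ROI voxel count.
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(S, n_vox) {
  out <- rl_features(S, n_vox, "glszm_", "zone")
  names(out) <- sub("short_zone", "small_zone", names(out))
  names(out) <- sub("long_zone", "large_zone", names(out))
  out
}

#' Neighbourhood grey-tone difference table
#'
#' For each valid voxel with at least one valid 26-neighbour, the
#' absolute difference between its level and the mean neighbour level is
#' accumulated per level.
#'
#' @param levels Integer grid (NA = invalid).
#' @param n_levels Ng.
#' @return List with vectors `n_i`, `p_i`, `s_i` (length Ng) and `n_valid`.
#' @export
ngtdm_table <- function(levels, n_levels) {
  offs <- neighbor_offsets_26()
  acc <- array(0, dim(levels)); cnt <- array(0, dim(levels))
  for (r in seq_len(nrow(offs))) {
    s <- shift3d(levels, offs[r, ], fill = NA)
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    cnt <- cnt + ok
  }
  use <- !is.na(levels) & cnt > 0
  diffv <- abs(levels[use] - acc[use] / cnt[use])
  lv <- levels[use]
  n_i <- tabulate(lv, nbins = n_levels)
  s_i <- as.numeric(tapply(diffv, factor(lv, levels = seq_len(n_levels)), sum))
  s_i[is.na(s_i)] <- 0
  nv <- sum(n_i)
  list(n_i = n_i, p_i = if (nv > 0) n_i / nv else n_i, s_i = s_i, n_valid = nv)
}

#' NGTDM features (5)
#' @param tb Table from [ngtdm_table()].
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(tb) {
  p <- tb$p_i; s <- tb$s_i; nv <- tb$n_valid
  pres <- which(p > 0)
  ngp <- length(pres)
  lev <- seq_along(p)
  coars <- if (sum(p * s) > 0) 1 / sum(p * s) else 1e6
  if (ngp > 1) {
    pi_ <- p[pres]; li <- lev[pres]; si <- s[pres]
    dif2 <- outer(li, li, function(a, b) (a - b)^2)
    contr <- sum(outer(pi_, pi_) * dif2) / (ngp * (ngp - 1)) * sum(si) / nv
    busy_den <- sum(abs(outer(li * pi_, li * pi_, `-`)))
    busy <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
    pij <- outer(pi_, pi_, `+`)
    sij <- outer(pi_ * si, pi_ * si, function(a, b) a + b)
    compl_ <- sum(abs(outer(li, li, `-`)) * sij / pij) / nv
    stren <- if (sum(si) > 0) sum(pij * dif2) / sum(si) else 0
  } else {
    contr <- 0; busy <- 0; compl_ <- 0; stren <- 0
  }
  c(ngtdm_coarseness = coars, ngtdm_contrast = contr, ngtdm_busyness = busy,
    ngtdm_complexity = compl_, ngtdm_strength = stren)
}

#' Neighbouring grey-level dependence matrix (coarseness parameter 0)
#'
#' Dependence count of a voxel = 1 + number of valid 26-neighbours with
#' exactly the same grey level.
#'
#' @param levels Integer grid (NA = invalid).
#' @param n_levels Ng.
#' @return Ng x 27 count matrix (columns = dependence count 1..27).
#' @export
ngldm_matrix <- function(levels, n_levels) {
  offs <- neighbor_offsets_26()
  dep <- array(0, dim(levels))
  for (r in seq_len(nrow(offs))) {
    s <- shift3d(levels, offs[r, ], fill = NA)
    dep <- dep + (!is.na(s) & !is.na(levels) & s == levels)
  }
  use <- !is.na(levels)
  k <- dep[use] + 1
  lv <- levels[use]
  counts <- matrix(tabulate((lv - 1L) * 27L + k, nbins = n_levels * 27L),
                   n_levels, 27L, byrow = TRUE)
  counts
}

#' NGLDM features (10)
#' @param D Count matrix from [ngldm_matrix()].
#' @return Named numeric vector of length 10.
#' @export
ngldm_features <- function(D) {
  Ns <- sum(D)
  if (Ns == 0) D1 <- D else D1 <- D / Ns
  i <- row(D); j <- col(D)
  ri <- rowSums(D); rj <- colSums(D)
  p <- D1[D1 > 0]
  c(ngldm_low_dependence_emphasis = sum(rj / seq_along(rj)^2) / Ns,
    ngldm_high_dependence_emphasis = sum(rj * seq_along(rj)^2) / Ns,
    ngldm_low_grey_level_count_emphasis = sum(ri / seq_along(ri)^2) / Ns,
    ngldm_high_grey_level_count_emphasis = sum(ri * seq_along(ri)^2) / Ns,
    ngldm_low_dependence_low_grey_level_emphasis = sum(D / (i^2 * j^2)) / Ns,
    ngldm_low_dependence_high_grey_level_emphasis = sum(D * i^2 / j^2) / Ns,
    ngldm_high_dependence_low_grey_level_emphasis = sum(D * j^2 / i^2) / Ns,
    ngldm_high_dependence_high_grey_level_emphasis = sum(D * i^2 * j^2) / Ns,
    ngldm_dependence_count_nonuniformity = sum(rj^2) / Ns,
    ngldm_dependence_count_entropy = -sum(p * log2(p)))
}

#' Extract all 72 texture features from a discretized grid
#'
#' @param levels Integer grid from [discretize()] (NA = invalid).
#' @param n_levels Number of grey levels (defaults to the `n_levels`
#'   attribute of `levels`).
#' @return Named numeric vector of length 72 (GLCM 25, GLRLM 16,
#'   GLSZM 16, NGTDM 5, NGLDM 10).
#' @export
extract_texture <- function(levels, n_levels = attr(levels, "n_levels")) {
  if (is.null(n_levels) || n_levels < 1L)
    stopf("n_levels missing or invalid for texture extraction")
  n_vox <- sum(!is.na(levels))
  if (n_vox < 2L) stopf("fewer than 2 valid voxels: texture undefined")
  c(glcm_features(glcm_matrix(levels, n_levels)),
    glrlm_features(glrlm_matrix(levels, n_levels), n_vox),
    glszm_features(glszm_matrix(levels, n_levels), n_vox),
    ngtdm_features(ngtdm_table(levels, n_levels)),
    ngldm_features(ngldm_matrix(levels, n_levels)))
}
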