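## The 14 spatial lymph-node-distribution (LNPT) features: distance
## statistics from the primary tumor to each node, volume-weighted
## variants, minimum-spanning-tree gaps between structures, a
## Calinski-Harabasz cluster count, and point-cloud elongation/flatness.
## All statistics use the population SD convention (single-element sets
## give 0), and all coordinates are physical (mm).

#' Build a structure set from a preprocessed volume
#'
#' @param v A `volume_with_masks` with `ln_labels` (see [merge_ln()]).
#' @return An object of class `structure_set`: PT voxel coordinates, a
#'   list of per-LN-component coordinate sets, and structure volumes.
#' @export
structure_set_from_volume <- function(v) {
  if (is.null(v$ln_labels)) v <- merge_ln(v)
  if (!any(v$pt_mask)) stopf("empty PT mask in structure set")
  if (v$n_ln_components < 1L) stopf("no LN components in structure set")
  vox <- prod(v$spacing)
  comps <- lapply(seq_len(v$n_ln_components), function(k)
    mask_coords_mm(v$ln_labels == k, v$spacing))
  structure_set(mask_coords_mm(v$pt_mask, v$spacing), comps, vox)
}

#' Construct a structure set from coordinate sets
#'
#' @param pt_voxels Matrix (n x 3) of PT voxel-center coordinates (mm).
#' @param ln_components List of per-component coordinate matrices.
#' @param voxel_volume Volume of one voxel (mm^3) used for structure
#'   volumes.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(pt_voxels, ln_components, voxel_volume = 1) {
  if (!nrow(pt_voxels)) stopf("PT must be non-empty")
  if (!length(ln_components)) stopf("at least one LN component required")
  structure(list(
    pt_voxels = pt_voxels, ln_components = ln_components,
    pt_volume = nrow(pt_voxels) * voxel_volume,
    ln_volumes = vapply(ln_components, nrow, 0L) * voxel_volume),
    class = "structure_set")
}

com_of <- function(m) colMeans(m)

ln_com_distances <- function(s) {
  pt_com <- com_of(s$pt_voxels)
  vapply(s$ln_components,
         function(m) sqrt(sum((com_of(m) - pt_com)^2)), 0)
}

#' Center-of-mass distance statistics (5 features)
#' @param s A `structure_set`.
#' @return Named vector: mean, SD, median, min, max of the PT-to-LN
#'   center-of-mass distances.
#' @export
com_distance_stats <- function(s) {
  d <- ln_com_distances(s)
  c(lnpt_com_dist_mean = mean(d), lnpt_com_dist_sd = sd_pop(d),
    lnpt_com_dist_median = stats::median(d), lnpt_com_dist_min = min(d),
    lnpt_com_dist_max = max(d))
}

## weighted mean / population SD with arbitrary non-negative weights
wmean_wsd <- function(x, w) {
  mu <- sum(w * x) / sum(w)
  c(mu, sqrt(sum(w * (x - mu)^2) / sum(w)))
}

#' Volume-weighted distance statistics (2 features)
#' @param s A `structure_set`.
#' @return Named vector: LN-volume-weighted mean and SD of the
#'   center-of-mass distances.
#' @export
weighted_distance_stats <- function(s) {
  d <- ln_com_distances(s)
  ws <- wmean_wsd(d, s$ln_volumes)
  c(lnpt_wdist_mean = ws[1], lnpt_wdist_sd = ws[2])
}

#' Tumor-volume-normalized weighted distance statistics (2 features)
#'
#' Distances are scaled by `v_i / V_PT` before the statistics, i.e. the
#' mean is `sum(d_i * v_i) / (n * V_PT)`-type rather than a reweighting
#' that a common factor would cancel; doubling the PT volume halves both
#' features.
#'
#' @param s A `structure_set`.
#' @return Named vector: `sum(d_i * v_i) / V_PT` and the population SD of
#'   the terms `d_i * v_i / V_PT`.
#' @export
normalized_weighted_distance_stats <- function(s) {
  d <- ln_com_distances(s) * s$ln_volumes / s$pt_volume
  c(lnpt_nwdist_mean = sum(d), lnpt_nwdist_sd = sd_pop(d))
}

## minimum voxel-center-to-voxel-center distance between two structures
min_gap <- function(a, b) {
  best <- Inf
  step <- max(1L, floor(2e6 / nrow(b)))
  for (ss in seq(1L, nrow(a), by = step)) {
    e <- min(nrow(a), ss + step - 1L)
    blk <- a[ss:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(b^2), `+`) - 2 * blk %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Minimum-spanning-tree gap features (2 features)
#'
#' Builds the complete graph over structures (PT plus each LN component;
#' edge weight = smallest surface-voxel-center distance between the two
#' structures), extracts the minimum spanning tree with Kruskal's
#' algorithm and returns the mean and maximum MST edge weight.
#'
#' @param s A `structure_set`.
#' @param include_pt Include the PT as a graph vertex (default TRUE).
#' @return Named vector of 2 features.
#' @export
mst_distance_features <- function(s, include_pt = TRUE) {
  pts <- s$ln_components
  if (include_pt) pts <- c(list(s$pt_voxels), pts)
  n <- length(pts)
  if (n < 2L) stopf("MST features need at least 2 structures")
  w <- mst_edge_weights(pts)
  c(lnpt_mst_mean = mean(w), lnpt_mst_max = max(w))
}

#' MST edge weights over a list of structures (Kruskal, union-find)
#' @noRd
mst_edge_weights <- function(pts) {
  n <- length(pts)
  edges <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    edges <- rbind(edges, c(i, j, min_gap(pts[[i]], pts[[j]])))
  edges <- edges[order(edges[, 3]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  picked <- numeric(0)
  for (r in seq_len(nrow(edges))) {
    ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
    if (ra != rb) { parent[ra] <- rb; picked <- c(picked, edges[r, 3]) }
    if (length(picked) == n - 1L) break
  }
  picked
}

#' Calinski-Harabasz cluster count of the LN point cloud (1 feature)
#'
#' Runs k-means (fixed internal seed, 10 restarts) on all LN voxel
#' coordinates for k = 2..k_max and returns the k maximizing the
#' Calinski-Harabasz index. A single compact cloud reports 1: since the
#' index is undefined at k = 1, a k = 2 split whose centroids are closer
#' than twice the mean within-cluster radius is rejected as spurious.
#'
#' @param s A `structure_set`.
#' @param k_max Largest k tried (default 6).
#' @return Named length-1 vector `lnpt_cluster_count`.
#' @export
cluster_count <- function(s, k_max = 6L) {
  X <- do.call(rbind, s$ln_components)
  n <- nrow(X)
  if (n < 4L || nrow(unique(X)) < 2L)
    return(c(lnpt_cluster_count = 1))
  ks <- 2:min(k_max, nrow(unique(X)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(202L)
  fits <- lapply(ks, function(k)
    suppressWarnings(stats::kmeans(X, k, nstart = 10, iter.max = 50)))
  ch <- vapply(seq_along(ks), function(q) {
    f <- fits[[q]]; k <- ks[q]
    if (f$tot.withinss <= 0) return(Inf)
    (f$betweenss / (k - 1)) / (f$tot.withinss / (n - k))
  }, 0)
  ## unimodality guard: the CH index is undefined at k = 1, so a split of
  ## a contiguous cloud must not report multimodality. If the two k = 2
  ## clusters are separated by less than twice the point pitch (median
  ## nearest-neighbour distance), the cut runs through one blob -> 1.
  f2 <- fits[[1]]
  a <- X[f2$cluster == 1L, , drop = FALSE]
  b <- X[f2$cluster == 2L, , drop = FALSE]
  samp <- X[seq(1L, n, length.out = min(n, 300L)), , drop = FALSE]
  d2 <- outer(rowSums(samp^2), rowSums(X^2), `+`) - 2 * samp %*% t(X)
  d2[d2 < 1e-9] <- Inf
  pitch <- stats::median(sqrt(apply(d2, 1, min)))
  if (min_gap(a, b) < 2 * pitch) return(c(lnpt_cluster_count = 1))
  c(lnpt_cluster_count = as.numeric(ks[which.max(ch)]))
}

#' Point-cloud elongation and flatness of PT plus LN (2 features)
#'
#' Eigenvalues l1 >= l2 >= l3 of the covariance of all PT and LN voxel
#' coordinates; elongation = sqrt(l2/l1), flatness = sqrt(l3/l1).
#'
#' @param s A `structure_set`.
#' @return Named vector of 2 features in (0, 1].
#' @export
pca_elongation_flatness <- function(s) {
  X <- rbind(s$pt_voxels, do.call(rbind, s$ln_components))
  if (nrow(X) < 4L) stopf("need at least 4 voxels for the PCA features")
  ev <- sort(pmax(eigen(stats::cov(X), symmetric = TRUE,
                        only.values = TRUE)$values, 0), decreasing = TRUE)
  if (ev[1] <= 0) return(c(lnpt_elongation = 0, lnpt_flatness = 0))
  c(lnpt_elongation = sqrt(ev[2] / ev[1]),
    lnpt_flatness = sqrt(ev[3] / ev[1]))
}

#' Extract all 14 LNPT features
#'
#' @param s A `structure_set`.
#' @return Named numeric vector of length 14 (5 + 2 + 2 + 2 + 1 + 2).
#' @export
extract_lnpt <- function(s) {
  stopifnot(inherits(s, "structure_set"))
  c(com_distance_stats(s),
    weighted_distance_stats(s),
    normalized_weighted_distance_stats(s),
    mst_distance_features(s),
    cluster_count(s),
    pca_elongation_flatness(s))
}
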