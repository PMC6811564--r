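## Morphological (shape) features: mesh-based volume/area, sphericity
## family, PCA axis lengths, diameter, local thickness.

## Corner offsets of a unit cell, order c0..c7.
.cube_corners <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

## Six-tetrahedra decomposition of the cube around the c0-c6 diagonal.
.cube_tets <- rbind(
  c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

#' Surface mesh of a binary mask by marching tetrahedra
#'
#' The mask is zero-padded, optionally smoothed with a 3x3x3 box filter
#' (sub-voxel surface placement; falls back to the raw binary field for
#' tiny masks that the smoothing would erase), and the 0.5 isosurface is
#' extracted per tetrahedron with linear edge interpolation. Triangles
#' are oriented outward.
#'
#' @param mask Binary 3D array.
#' @param spacing mm per axis.
#' @param smooth Apply the box pre-filter (default TRUE).
#' @return List with `area` (mm^2), `volume` (mm^3) and `n_triangles`.
#' @export
mesh_mask <- function(mask, spacing, smooth = TRUE) {
  if (!any(mask)) stopf("empty mask: no surface mesh")
  d <- dim(mask)
  f <- array(0, d + 2L)
  f[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask * 1.0
  if (smooth) {
    ## sub-voxel surface placement; digital-ball areas come out within
    ## ~2% of the continuum, at the price of eroding very small blobs
    ## (their mesh volume underestimates the voxel volume)
    fs <- box_smooth3(f)
    if (max(fs) > 0.5) f <- fs
  }
  dd <- dim(f)
  nc <- dd - 1L
  ncell <- prod(nc)
  corner_val <- vector("list", 8L)
  for (c8 in 1:8) {
    o <- .cube_corners[c8, ]
    corner_val[[c8]] <- as.numeric(
      f[(1L + o[1]):(nc[1] + o[1]), (1L + o[2]):(nc[2] + o[2]),
        (1L + o[3]):(nc[3] + o[3])])
  }
  grid0 <- as.matrix(expand.grid(i = seq_len(nc[1]), j = seq_len(nc[2]),
                                 k = seq_len(nc[3])))
  corner_pos <- function(c8, cells) {
    sweep(sweep(grid0[cells, , drop = FALSE] - 1,
                2, .cube_corners[c8, ], `+`), 2, spacing, `*`)
  }
  iso <- 0.5
  area <- 0; vol <- 0; ntri <- 0L
  cross3 <- function(a, b) cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1])
  add_tris <- function(p1, p2, p3, ref) {
    n <- cross3(p2 - p1, p3 - p1)
    flip <- rowSums(n * ref) < 0
    if (any(flip)) { tmp <- p2[flip, , drop = FALSE]
      p2[flip, ] <- p3[flip, , drop = FALSE]; p3[flip, ] <- tmp
      n[flip, ] <- -n[flip, , drop = FALSE] }
    area <<- area + sum(sqrt(rowSums(n^2))) / 2
    vol <<- vol + sum(rowSums(p1 * cross3(p2, p3))) / 6
    ntri <<- ntri + nrow(p1)
  }
  interp <- function(pa, va, pb, vb) {
    t <- (iso - va) / (vb - va)
    pa + (pb - pa) * t
  }
  for (tt in seq_len(nrow(.cube_tets))) {
    tet <- .cube_tets[tt, ]
    v <- lapply(tet, function(c8) corner_val[[c8]])
    ins <- lapply(v, function(x) x > iso)
    code <- ins[[1]] + 2L * ins[[2]] + 4L * ins[[3]] + 8L * ins[[4]]
    for (cs in 1:14) {
      cells <- which(code == cs)
      if (!length(cells)) next
      b <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
      inside <- which(b); outside <- which(!b)
      P <- lapply(1:4, function(q) corner_pos(tet[q], cells))
      V <- lapply(1:4, function(q) v[[q]][cells])
      cen <- function(ix) Reduce(`+`, P[ix]) / length(ix)
      ref <- cen(outside) - cen(inside)
      if (length(inside) == 1L || length(inside) == 3L) {
        apex <- if (length(inside) == 1L) inside else outside
        rest <- setdiff(1:4, apex)
        q1 <- interp(P[[apex]], V[[apex]], P[[rest[1]]], V[[rest[1]]])
        q2 <- interp(P[[apex]], V[[apex]], P[[rest[2]]], V[[rest[2]]])
        q3 <- interp(P[[apex]], V[[apex]], P[[rest[3]]], V[[rest[3]]])
        add_tris(q1, q2, q3, ref)
      } else {  # two in, two out: quad split into two triangles
        A <- inside[1]; B <- inside[2]; C <- outside[1]; D <- outside[2]
        ac <- interp(P[[A]], V[[A]], P[[C]], V[[C]])
        ad <- interp(P[[A]], V[[A]], P[[D]], V[[D]])
        bc <- interp(P[[B]], V[[B]], P[[C]], V[[C]])
        bd <- interp(P[[B]], V[[B]], P[[D]], V[[D]])
        add_tris(ac, ad, bd, ref)
        add_tris(ac, bd, bc, ref)
      }
    }
  }
  list(area = area, volume = abs(vol), n_triangles = ntri)
}

## Boundary voxels: mask voxels with at least one 6-neighbour outside.
boundary_voxels <- function(mask) {
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  b <- array(FALSE, dim(mask))
  for (r in 1:6)
    b <- b | (mask & !shift3d(mask, offs[r, ], fill = FALSE))
  b
}

## Largest pairwise distance between boundary voxel centers, chunked.
max_diameter <- function(coords) {
  n <- nrow(coords)
  if (n == 1L) return(0)
  best <- 0
  step <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    blk <- coords[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(coords^2), `+`) -
      2 * blk %*% t(coords)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Extract the 18 morphological features of a ROI
#'
#' Computed on the full (unwindowed) mask in physical units (mm). Axis
#' lengths follow the 4*sqrt(eigenvalue) convention on the voxel-center
#' covariance; elongation and flatness are sqrt ratios of the second and
#' third eigenvalue to the first. Local thickness is twice the Euclidean
#' distance transform evaluated at medial voxels (local EDT maxima).
#'
#' @param mask Binary 3D array (non-empty).
#' @param spacing mm per axis.
#' @param image Optional HU grid for the center-of-mass shift; without it
#'   the shift is 0.
#' @return Named numeric vector of length 18.
#' @export
extract_shape <- function(mask, spacing, image = NULL) {
  if (!any(mask)) stopf("empty mask: shape features undefined")
  msh <- mesh_mask(mask, spacing)
  V <- msh$volume; A <- msh$area
  n_vox <- sum(mask)
  vox_vol <- n_vox * prod(spacing)
  coords <- mask_coords_mm(mask, spacing)
  ## PCA axes
  if (n_vox >= 2) {
    cv <- stats::cov(coords) * (n_vox - 1) / n_vox
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  ## thickness via local EDT maxima
  edt <- distance_transform(mask, spacing)
  is_medial <- mask
  for (r in seq_len(nrow(neighbor_offsets_26()))) {
    nb <- shift3d(edt, neighbor_offsets_26()[r, ], fill = 0)
    is_medial <- is_medial & (edt >= nb)
  }
  th <- 2 * edt[is_medial]
  com_shift <- 0
  if (!is.null(image)) {
    ## weights shifted to be non-negative so mixed-sign HU values cannot
    ## produce a degenerate weighted center
    w <- image[mask != 0]
    w <- w - min(w)
    if (sum(w) > 0) {
      com_g <- colMeans(coords)
      com_i <- colSums(coords * w) / sum(w)
      com_shift <- sqrt(sum((com_g - com_i)^2))
    }
  }
  sph <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  c(shape_mesh_volume = V,
    shape_voxel_volume = vox_vol,
    shape_surface_area = A,
    shape_surface_to_volume_ratio = A / V,
    shape_sphericity = sph,
    shape_spherical_disproportion = 1 / sph,
    shape_compactness1 = V / (sqrt(pi) * A^(3 / 2)),
    shape_compactness2 = 36 * pi * V^2 / A^3,
    shape_asphericity = (A^3 / (36 * pi * V^2))^(1 / 3) - 1,
    shape_max_3d_diameter = max_diameter(mask_coords_mm(boundary_voxels(mask),
                                                        spacing)),
    shape_major_axis = 4 * sqrt(ev[1]),
    shape_minor_axis = 4 * sqrt(ev[2]),
    shape_least_axis = 4 * sqrt(ev[3]),
    shape_elongation = elong,
    shape_flatness = flat,
    shape_com_shift = com_shift,
    shape_thickness_mean = mean(th),
    shape_thickness_sd = sd_pop(th))
}
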