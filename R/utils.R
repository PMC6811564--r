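## Internal array / geometry helpers shared across modules.

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Shift a 3D array by an integer offset, padding with `fill`.
#'
#' Element [i,j,k] of the result is a[i - dx, j - dy, k - dz] where the
#' source index exists, `fill` elsewhere.
#' @noRd
shift3d <- function(a, off, fill = NA) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1L + o):d[ax]
      src[[ax]] <- 1L:(d[ax] - o)
    } else {
      dst[[ax]] <- 1L:(d[ax] + o)
      src[[ax]] <- (1L - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## The 26-neighbourhood offsets and the 13 unique (half-space) directions.
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

direction_offsets_13 <- function() {
  g <- neighbor_offsets_26()
  ## keep one of each +/- pair: first nonzero component positive
  keep <- apply(g, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  g[keep, , drop = FALSE]
}

#' Voxel-center physical coordinates (mm) of mask voxels (0-based indices).
#' @noRd
mask_coords_mm <- function(mask, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, `*`)
}

#' Population standard deviation (divide by n); 0 for a single element.
#' @noRd
sd_pop <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Box (mean) filter of a 3D array with a 3x3x3 kernel, replicated edges.
#' @noRd
box_smooth3 <- function(a) {
  d <- dim(a)
  acc <- array(0, d)
  cnt <- array(0, d)
  offs <- rbind(c(0, 0, 0), neighbor_offsets_26())
  for (r in seq_len(nrow(offs))) {
    s <- shift3d(a, offs[r, ], fill = NA)
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    cnt <- cnt + ok
  }
  acc / cnt
}

#' 1D squared Euclidean distance transform (lower envelope of parabolas).
#' f holds squared distances at sample sites (Inf where no site yet),
#' w the sample spacing. Positions are in physical units.
#' @noRd
dt1d <- function(f, w = 1) {
  n <- length(f)
  finite <- which(is.finite(f))
  if (length(finite) == 0L || n == 1L) return(f)
  x <- seq_len(n) * w
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- finite[1L]; z[1L] <- -Inf; z[2L] <- Inf
  if (length(finite) > 1L) {
    for (q in finite[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
        if (s <= z[k]) {
          k <- k - 1L
        } else {
          k <- k + 1L
          v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
          break
        }
      }
    }
  }
  d <- numeric(n); j <- 1L
  for (q in 1:n) {
    while (z[j + 1L] < x[q]) j <- j + 1L
    p <- v[j]
    d[q] <- (x[q] - x[p])^2 + f[p]
  }
  d
}

#' Exact Euclidean distance transform of a binary 3D mask (distance from
#' each inside voxel to the nearest outside voxel), in mm. Outside the
#' grid counts as background.
#' @noRd
distance_transform <- function(mask, spacing) {
  d <- dim(mask)
  ## pad with a background layer so the grid boundary acts as background
  f <- array(0, d + 2L)
  f[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- ifelse(mask != 0, Inf, 0)
  dd <- dim(f)
  for (j in seq_len(dd[2])) for (k in seq_len(dd[3]))
    f[, j, k] <- dt1d(f[, j, k], spacing[1])
  for (i in seq_len(dd[1])) for (k in seq_len(dd[3]))
    f[i, , k] <- dt1d(f[i, , k], spacing[2])
  for (i in seq_len(dd[1])) for (j in seq_len(dd[2]))
    f[i, j, ] <- dt1d(f[i, j, ], spacing[3])
  sqrt(f[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)])
}

#' Derive a stage-specific seed from a global seed and a stage name.
#' Deterministic, stays below 2^31.
#' @noRd
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 100000L) * 17477L + (h %% 17477L)
}
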