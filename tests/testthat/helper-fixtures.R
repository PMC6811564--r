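## Shared fixtures and independent brute-force oracles.

## Digital ball mask of radius r (voxels) centered in an n^3 grid.
mkball <- function(r, n = ceiling(2 * r) + 5) {
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  ctr <- rep((n + 1) / 2, 3)
  array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= r, rep(n, 3))
}

## Coordinates (mm) of a ball of radius r centered at ctr, voxel pitch sp.
mkball_coords <- function(ctr, r, sp = 1) {
  g <- as.matrix(expand.grid(x = seq(ctr[1] - r - 1, ctr[1] + r + 1, by = sp),
                             y = seq(ctr[2] - r - 1, ctr[2] + r + 1, by = sp),
                             z = seq(ctr[3] - r - 1, ctr[3] + r + 1, by = sp)))
  g[sqrt(rowSums(sweep(g, 2, ctr)^2)) <= r, , drop = FALSE]
}

## A minimal volume_with_masks for preprocessing tests.
mkvol <- function(pt, ln = array(FALSE, dim(pt)), image = NULL,
                  spacing = c(1, 1, 1), artifact_slices = integer(0)) {
  if (is.null(image)) image <- array(60, dim(pt))
  structure(list(patient_id = "T001", image = image, pt_mask = pt,
                 ln_mask = ln, spacing = spacing,
                 artifact_slices = artifact_slices, eligible = NA),
            class = "volume_with_masks")
}

## --- brute-force texture oracles (deliberately naive) -------------------

bf_glcm <- function(lv, ng) {
  dirs <- lnradiomics:::direction_offsets_13()
  d <- dim(lv)
  acc <- matrix(0, ng, ng); used <- 0
  idx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  for (r in seq_len(nrow(dirs))) {
    cnt <- matrix(0, ng, ng)
    for (q in seq_len(nrow(idx))) {
      a <- idx[q, ]; b <- a + dirs[r, ]
      if (any(b < 1) || any(b > d)) next
      va <- lv[a[1], a[2], a[3]]; vb <- lv[b[1], b[2], b[3]]
      if (is.na(va) || is.na(vb)) next
      cnt[va, vb] <- cnt[va, vb] + 1
      cnt[vb, va] <- cnt[vb, va] + 1
    }
    if (sum(cnt) > 0) { acc <- acc + cnt / sum(cnt); used <- used + 1 }
  }
  acc / used
}

## enumerate every maximal run voxel-by-voxel
bf_glrlm <- function(lv, ng) {
  dirs <- lnradiomics:::direction_offsets_13()
  d <- dim(lv)
  maxlen <- max(d)
  counts <- matrix(0, ng, maxlen)
  at <- function(p) if (any(p < 1) || any(p > d)) NA else lv[p[1], p[2], p[3]]
  idx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    for (q in seq_len(nrow(idx))) {
      p <- idx[q, ]
      v <- at(p)
      if (is.na(v)) next
      prev <- at(p - off)
      if (!is.na(prev) && prev == v) next   # not a run start
      len <- 1
      nxt <- p + off
      while (!is.na(at(nxt)) && at(nxt) == v) { len <- len + 1; nxt <- nxt + off }
      counts[v, len] <- counts[v, len] + 1
    }
  }
  counts
}

## recursive flood fill of equal-level 26-connected zones
bf_glszm <- function(lv, ng) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  offs <- lnradiomics:::neighbor_offsets_26()
  sizes <- list()
  idx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  for (q in seq_len(nrow(idx))) {
    p <- idx[q, ]
    if (seen[p[1], p[2], p[3]] || is.na(lv[p[1], p[2], p[3]])) next
    v <- lv[p[1], p[2], p[3]]
    stack <- list(p); size <- 0
    seen[p[1], p[2], p[3]] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        nb <- cur + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        if (seen[nb[1], nb[2], nb[3]]) next
        if (is.na(lv[nb[1], nb[2], nb[3]]) || lv[nb[1], nb[2], nb[3]] != v) next
        seen[nb[1], nb[2], nb[3]] <- TRUE
        stack[[length(stack) + 1L]] <- nb
      }
    }
    sizes[[length(sizes) + 1L]] <- c(v, size)
  }
  smax <- max(vapply(sizes, `[`, 0, 2))
  counts <- matrix(0, ng, smax)
  for (z in sizes) counts[z[1], z[2]] <- counts[z[1], z[2]] + 1
  counts
}

## exhaustive minimum spanning tree over <= 5 structures: try all edge
## subsets of size n-1 and keep the cheapest connected one
bf_mst_weights <- function(pts) {
  n <- length(pts)
  gap <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
    sqrt(max(min(d2), 0))
  }
  ed <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    ed <- rbind(ed, c(i, j, gap(pts[[i]], pts[[j]])))
  best <- NULL; best_w <- Inf
  for (comb in utils::combn(nrow(ed), n - 1, simplify = FALSE)) {
    sub <- ed[comb, , drop = FALSE]
    ## connectivity check by label merging
    lab <- seq_len(n)
    for (r in seq_len(nrow(sub))) {
      la <- lab[sub[r, 1]]; lb <- lab[sub[r, 2]]
      lab[lab == lb] <- la
    }
    if (length(unique(lab)) > 1L) next
    w <- sum(sub[, 3])
    if (w < best_w) { best_w <- w; best <- sub[, 3] }
  }
  sort(best)
}

## Calinski-Harabasz index by its definition on given labels
ch_index <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  gm <- colMeans(X)
  between <- 0; within <- 0
  for (g in unique(labels)) {
    Xi <- X[labels == g, , drop = FALSE]
    ci <- colMeans(Xi)
    between <- between + nrow(Xi) * sum((ci - gm)^2)
    within <- within + sum(sweep(Xi, 2, ci)^2)
  }
  (between / (k - 1)) / (within / (n - k))
}
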