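test_that("center-of-mass distance statistics match hand computations", {
  pt <- mkball_coords(c(0, 0, 0), 4)
  s1 <- structure_set(pt, list(mkball_coords(c(3, 4, 0) * 4, 3)))
  f1 <- com_distance_stats(s1)
  expect_equal(unname(f1), c(20, 0, 20, 20, 20), tolerance = 1e-9)
  s2 <- structure_set(pt, list(mkball_coords(c(10, 0, 0), 2),
                               mkball_coords(c(0, 20, 0), 2)))
  f2 <- com_distance_stats(s2)
  expect_equal(f2[["lnpt_com_dist_mean"]], 15, tolerance = 1e-9)
  expect_equal(f2[["lnpt_com_dist_sd"]], 5, tolerance = 1e-9)  # population SD
  expect_equal(f2[["lnpt_com_dist_min"]], 10, tolerance = 1e-9)
  expect_equal(f2[["lnpt_com_dist_max"]], 20, tolerance = 1e-9)
  ## coincident centers give distance zero
  s0 <- structure_set(pt, list(mkball_coords(c(0, 0, 0), 2)))
  expect_equal(com_distance_stats(s0)[["lnpt_com_dist_min"]], 0)
})

test_that("volume weighting follows the pinned formulas", {
  pt <- mkball_coords(c(0, 0, 0), 4)
  s <- structure_set(pt, list(mkball_coords(c(10, 0, 0), 2),
                              mkball_coords(c(0, 20, 0), 2)))
  s$ln_volumes <- c(1, 9)
  expect_equal(weighted_distance_stats(s)[["lnpt_wdist_mean"]], 19,
               tolerance = 1e-9)
  ## equal volumes reduce to the unweighted mean
  s$ln_volumes <- c(5, 5)
  expect_equal(weighted_distance_stats(s)[["lnpt_wdist_mean"]], 15,
               tolerance = 1e-9)
  ## normalization: V_PT = sum(v) reproduces the weighted mean
  s$ln_volumes <- c(1, 9); s$pt_volume <- 10
  expect_equal(normalized_weighted_distance_stats(s)[["lnpt_nwdist_mean"]], 19,
               tolerance = 1e-9)
  ## doubling the tumor volume halves the feature
  s2 <- s; s2$pt_volume <- 20
  expect_equal(normalized_weighted_distance_stats(s2)[["lnpt_nwdist_mean"]],
               9.5, tolerance = 1e-9)
  ## single LN with v = V_PT at 10 mm gives exactly 10
  s3 <- structure_set(pt, list(mkball_coords(c(10, 0, 0), 2)))
  s3$ln_volumes <- 77; s3$pt_volume <- 77
  f3 <- normalized_weighted_distance_stats(s3)
  expect_equal(f3[["lnpt_nwdist_mean"]], 10, tolerance = 1e-9)
  expect_equal(f3[["lnpt_nwdist_sd"]], 0)
  expect_equal(weighted_distance_stats(s3)[["lnpt_wdist_sd"]], 0)
})

test_that("MST features agree with exhaustive spanning-tree search", {
  pt <- mkball_coords(c(0, 0, 0), 3)
  ## collinear structures with surface gaps ~5 and ~7
  lns <- list(mkball_coords(c(11, 0, 0), 3), mkball_coords(c(24, 0, 0), 3))
  s <- structure_set(pt, lns)
  f <- mst_distance_features(s)
  bf <- bf_mst_weights(c(list(pt), lns))
  expect_equal(unname(f), c(mean(bf), max(bf)), tolerance = 1e-9)
  expect_length(bf, 2L)          # edges = structures - 1
  ## single LN: both features equal the single gap
  s1 <- structure_set(pt, list(mkball_coords(c(12, 0, 0), 3)))
  f1 <- mst_distance_features(s1)
  expect_equal(f1[["lnpt_mst_mean"]], f1[["lnpt_mst_max"]])
  ## 5 structures: Kruskal matches brute force
  lns5 <- list(mkball_coords(c(12, 0, 0), 2), mkball_coords(c(0, 14, 0), 2),
               mkball_coords(c(-13, 2, 3), 2), mkball_coords(c(4, -11, 7), 2))
  s5 <- structure_set(pt, lns5)
  bf5 <- bf_mst_weights(c(list(pt), lns5))
  f5 <- mst_distance_features(s5)
  expect_equal(f5[["lnpt_mst_mean"]], mean(bf5), tolerance = 1e-9)
  expect_equal(f5[["lnpt_mst_max"]], max(bf5), tolerance = 1e-9)
  ## voxel-center convention: structures touching face-to-face have gap
  ## equal to one spacing step
  a <- matrix(c(0, 0, 0), 1); b <- matrix(c(1, 0, 0), 1)
  st <- structure_set(rbind(a, a + c(0, 1, 0)), list(rbind(b, b + c(0, 1, 0))))
  expect_equal(mst_distance_features(st)[["lnpt_mst_mean"]], 1)
})

test_that("Calinski-Harabasz cluster counts match direct index computation", {
  pt <- mkball_coords(c(0, 0, 0), 4)
  blobs <- list(mkball_coords(c(25, 0, 0), 3), mkball_coords(c(-25, 0, 0), 3),
                mkball_coords(c(0, 28, 3), 3))
  s <- structure_set(pt, blobs)
  expect_equal(unname(cluster_count(s)), 3)
  ## direct CH computation on the true labels beats a k = 2 grouping
  X <- do.call(rbind, blobs)
  lab3 <- rep(1:3, vapply(blobs, nrow, 0L))
  lab2 <- as.integer(lab3 > 1)
  expect_gt(ch_index(X, lab3), ch_index(X, lab2))
  ## one compact blob reports 1 via the degenerate rule
  expect_equal(unname(cluster_count(structure_set(pt, list(mkball_coords(c(12, 0, 0), 4))))), 1)
  ## two well-separated blobs report 2
  s2 <- structure_set(pt, list(mkball_coords(c(20, 0, 0), 3),
                               mkball_coords(c(-20, 5, 0), 3)))
  expect_equal(unname(cluster_count(s2)), 2)
})

test_that("PCA elongation/flatness follow the coordinate covariance", {
  pt <- mkball_coords(c(0, 0, 0), 5)
  s <- structure_set(pt, list(mkball_coords(c(30, 0, 0), 3)))
  f <- pca_elongation_flatness(s)
  X <- rbind(s$pt_voxels, s$ln_components[[1]])
  ev <- sort(eigen(cov(X), only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(f[["lnpt_elongation"]], sqrt(ev[2] / ev[1]), tolerance = 1e-12)
  expect_lt(f[["lnpt_elongation"]], 1)
  ## a single ball is isotropic
  fb <- pca_elongation_flatness(structure_set(pt, list(pt + 20)))
  expect_lt(fb[["lnpt_flatness"]], 1 + 1e-9)
})

test_that("the 14 LNPT features obey rigid-motion and scaling symmetries", {
  pt <- mkball_coords(c(0, 0, 0), 4)
  s <- structure_set(pt, list(mkball_coords(c(25, 0, 0), 3),
                              mkball_coords(c(0, 28, 3), 3)))
  f <- extract_lnpt(s)
  expect_length(f, 14L)
  expect_equal(sum(startsWith(names(f), "lnpt_com_dist")), 5L)
  expect_equal(sum(startsWith(names(f), "lnpt_wdist")), 2L)
  expect_equal(sum(startsWith(names(f), "lnpt_nwdist")), 2L)
  expect_equal(sum(startsWith(names(f), "lnpt_mst")), 2L)
  apply_rigid <- function(s, R = diag(3), t = c(0, 0, 0)) {
    tf <- function(m) sweep(m %*% t(R), 2, t, `+`)
    s$pt_voxels <- tf(s$pt_voxels)
    s$ln_components <- lapply(s$ln_components, tf)
    s
  }
  ## translation
  expect_equal(extract_lnpt(apply_rigid(s, t = c(7.3, -2.1, 11))), f,
               tolerance = 1e-9)
  ## rotation (orthonormal matrix)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(extract_lnpt(apply_rigid(s, R = R)), f, tolerance = 1e-9)
  ## scaling: distances scale, ratios and counts do not
  s3 <- s
  s3$pt_voxels <- s$pt_voxels * 3
  s3$ln_components <- lapply(s$ln_components, function(m) m * 3)
  f3 <- extract_lnpt(s3)
  dist_feats <- grep("dist|mst", names(f))
  expect_equal(unname(f3[dist_feats]), unname(f[dist_feats] * 3),
               tolerance = 1e-9)
  expect_equal(f3[["lnpt_elongation"]], f[["lnpt_elongation"]], tolerance = 1e-9)
  expect_equal(f3[["lnpt_cluster_count"]], f[["lnpt_cluster_count"]])
  ## single-LN degenerate: SD-type features zero, cluster count one
  s1 <- structure_set(pt, list(mkball_coords(c(15, 0, 0), 3)))
  f1 <- extract_lnpt(s1)
  expect_equal(unname(f1[c("lnpt_com_dist_sd", "lnpt_wdist_sd",
                           "lnpt_nwdist_sd")]), c(0, 0, 0))
  expect_equal(f1[["lnpt_cluster_count"]], 1)
})
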