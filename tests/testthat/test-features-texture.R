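test_that("texture matrices equal brute-force enumeration on small grids", {
  for (seed in 1:3) {
    set.seed(seed)
    lv <- array(sample(1:4, 64, TRUE), c(4, 4, 4))
    lv[sample(64, 12)] <- NA
    expect_equal(glcm_matrix(lv, 4L), bf_glcm(lv, 4L), tolerance = 1e-12)
    got_rl <- glrlm_matrix(lv, 4L)
    expect_equal(unclass(got_rl)[, seq_len(ncol(got_rl))],
                 bf_glrlm(lv, 4L), ignore_attr = TRUE)
    got_sz <- glszm_matrix(lv, 4L)
    want_sz <- bf_glszm(lv, 4L)
    expect_equal(got_sz[, seq_len(ncol(want_sz)), drop = FALSE], want_sz,
                 ignore_attr = TRUE)
    expect_equal(sum(got_sz[, seq_len(ncol(got_sz))] %*% seq_len(ncol(got_sz))),
                 sum(!is.na(lv)))
  }
})

test_that("hand-checkable checkerboard co-occurrence probabilities", {
  lv <- array(c(1L, 2L, 2L, 1L), c(2, 2, 1))
  P <- glcm_matrix(lv, 2L)
  ## in-plane axis pairs are all unequal, the two diagonals all equal;
  ## brute force over the 13 offsets is the reference
  expect_equal(P, bf_glcm(lv, 2L), tolerance = 1e-12)
  fx <- glcm_features(P)
  H <- -sum(P[P > 0] * log2(P[P > 0]))
  expect_equal(fx[["glcm_entropy"]], H)
})

test_that("constant regions give degenerate texture limits", {
  lv <- array(1L, c(3, 3, 3)); attr(lv, "n_levels") <- 10L
  tx <- extract_texture(lv)
  expect_length(tx, 72L)
  expect_equal(tx[["glcm_entropy"]], 0)
  expect_equal(tx[["ngtdm_complexity"]], 0)
  expect_equal(tx[["ngtdm_contrast"]], 0)
  expect_equal(tx[["glszm_zone_entropy"]], 0)
  expect_equal(tx[["glcm_angular_second_moment"]], 1)
  expect_true(all(is.finite(tx)))
})

test_that("texture features are invariant under axis-aligned rotations", {
  set.seed(9)
  lv <- array(sample(1:5, 125, TRUE), c(5, 5, 5))
  lv[sample(125, 20)] <- NA
  attr(lv, "n_levels") <- 5L
  base <- extract_texture(lv)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    rot <- aperm(lv, perm); attr(rot, "n_levels") <- 5L
    expect_equal(extract_texture(rot), base, tolerance = 1e-12)
  }
})

test_that("NGLDM dependence counts partition the ROI", {
  set.seed(3)
  lv <- array(sample(1:3, 27, TRUE), c(3, 3, 3))
  D <- ngldm_matrix(lv, 3L)
  expect_equal(sum(D), 27)
  ## every voxel of a constant grid has the full dependence count
  lvc <- array(2L, c(3, 3, 3))
  Dc <- ngldm_matrix(lvc, 3L)
  expect_equal(Dc[2, 8], 8)   # corners: 7 neighbours + itself
  expect_equal(sum(Dc[2, ]), 27)
})
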