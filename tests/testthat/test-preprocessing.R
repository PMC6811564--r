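test_that("artifact slice removal zeroes contours but not the image", {
  pt <- array(FALSE, c(6, 6, 6)); pt[2:5, 2:5, 2:4] <- TRUE  # 48 voxels
  v <- mkvol(pt, artifact_slices = 2L)
  out <- remove_artifact_slices(v)
  expect_equal(sum(out$pt_mask), 48 - 16)
  expect_identical(out$image, v$image)
  v0 <- mkvol(pt)
  expect_identical(remove_artifact_slices(v0)$pt_mask, pt)
  ## removing every PT slice empties the mask
  v2 <- mkvol(pt, artifact_slices = 2:4)
  expect_equal(sum(remove_artifact_slices(v2)$pt_mask), 0)
})

test_that("eligibility applies the strict less-than-50% rule", {
  pt <- array(FALSE, c(5, 5, 10))
  pt[1:5, 1:4, 1:5] <- TRUE  # 100 voxels, 20 per slice
  expect_true(check_eligibility(mkvol(pt)))
  ## 40/100 on artifact slices -> eligible
  el <- check_eligibility(mkvol(pt, artifact_slices = 1:2))
  expect_true(el)
  expect_equal(attr(el, "artifact_fraction"), 0.4)
  ## exactly 50% -> NOT eligible
  el50 <- check_eligibility(mkvol(pt, artifact_slices = c(1:2, 3L)))
  expect_equal(attr(el50, "artifact_fraction"), 0.6)
  expect_false(el50)
  pt2 <- pt; pt2[, , 4:5] <- FALSE   # 60 voxels, slices 1:3
  ## fraction on slices 1,2 of 60 voxels is 40/60; build exact half instead
  pt3 <- array(FALSE, c(5, 5, 4)); pt3[1:5, 1:4, 1:4] <- TRUE
  expect_false(check_eligibility(mkvol(pt3, artifact_slices = 1:2)))
  expect_error(check_eligibility(mkvol(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("eligibility is monotone in the artifact set", {
  pt <- array(FALSE, c(5, 5, 8)); pt[2:4, 2:4, 2:7] <- TRUE
  fr <- function(sl) attr(check_eligibility(mkvol(pt, artifact_slices = sl)),
                          "artifact_fraction")
  fracs <- vapply(1:7, function(k) fr(seq_len(k)), 0)
  expect_true(all(diff(fracs) >= 0))
})

test_that("resampling preserves volume and extent of convex masks", {
  ball <- mkball(12, 31)
  v <- mkvol(ball)
  out <- resample_volume(v)
  va <- 4 / 3 * pi * 12^3
  expect_equal(out$spacing, rep(3.3, 3))
  expect_lt(abs(sum(out$pt_mask) * 3.3^3 - va) / va, 0.15)
  ## anisotropic in-plane 0.98 mm, slice thickness 2.0 mm
  v2 <- mkvol(ball, spacing = c(0.98, 0.98, 2.0))
  out2 <- resample_volume(v2)
  ext_in <- (dim(ball) - 1) * v2$spacing
  ext_out <- (dim(out2$image) - 1) * 3.3
  expect_true(all(abs(ext_in - ext_out) <= 3.3))
  ## identity resample: cubic 3.3 mm input keeps voxel values
  v3 <- mkvol(ball[1:10, 1:10, 1:10], spacing = rep(3.3, 3),
              image = array(rnorm(1000), c(10, 10, 10)))
  out3 <- resample_volume(v3)
  expect_equal(out3$image, v3$image, tolerance = 1e-12)
})

test_that("HU windowing excludes voxels without touching the shape mask", {
  img <- array(50, c(4, 4, 4))
  img[1:2, , ] <- 1000          # artifact streak half
  pt <- array(TRUE, c(4, 4, 4))
  v <- window_hu(mkvol(pt, image = img))
  expect_equal(sum(v$valid_mask & pt), 32)
  expect_identical(v$pt_mask, pt)
  expect_equal(mean(img[v$valid_mask & pt]), 50)
  ## closed interval: both boundary values kept
  img2 <- array(c(-20, 180, -20.5, 180.5), c(4, 4, 4))
  v2 <- window_hu(mkvol(pt, image = img2))
  expect_true(all(v2$valid_mask[img2 == -20 | img2 == 180]))
  expect_false(any(v2$valid_mask[img2 < -20 | img2 > 180]))
})

test_that("LN merging unions components and keeps labels", {
  ln <- array(FALSE, c(12, 12, 6))
  ln[1:2, 1:5, 1] <- TRUE        # 10 voxels
  ln[5:8, 1:5, 2] <- TRUE        # 20 voxels
  ln[9:11, 3:7, 4:5] <- TRUE     # 30 voxels
  v <- merge_ln(mkvol(array(FALSE, dim(ln)), ln = ln))
  expect_equal(v$n_ln_components, 3L)
  expect_equal(sum(v$ln_mask), 60)
  expect_setequal(tabulate(v$ln_labels[v$ln_labels > 0]), c(10, 20, 30))
  ## face-touching components merge under 26-connectivity
  ln2 <- array(FALSE, c(6, 6, 6)); ln2[1:2, 1, 1] <- TRUE; ln2[3, 1, 1] <- TRUE
  expect_equal(max(label_components_26(ln2)), 1L)
  ## single component is identity
  one <- array(FALSE, c(6, 6, 6)); one[2:4, 2:4, 2:4] <- TRUE
  v3 <- merge_ln(mkvol(array(FALSE, dim(one)), ln = one))
  expect_equal(v3$n_ln_components, 1L)
  expect_identical(v3$ln_mask, one)
})
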