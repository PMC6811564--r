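test_that("digital balls recover the continuum shape descriptors", {
  sf <- extract_shape(mkball(10, 25), c(1, 1, 1))
  expect_length(sf, 18L)
  expect_gte(sf[["shape_sphericity"]], 0.95)
  expect_lte(sf[["shape_sphericity"]], 1.0)
  expect_gte(sf[["shape_spherical_disproportion"]], 1.0)
  expect_lte(sf[["shape_spherical_disproportion"]], 1.05)
  ## thickness of a ball is nearly constant (SD small vs mean)
  expect_lt(sf[["shape_thickness_sd"]] / sf[["shape_thickness_mean"]], 0.1)
  ## diameter and axes near 2r and the uniform-ball 4*sqrt(r^2/5)
  expect_equal(sf[["shape_max_3d_diameter"]], 20, tolerance = 0.05)
  expect_equal(sf[["shape_major_axis"]], 4 * 10 / sqrt(5), tolerance = 0.05)
  expect_equal(sf[["shape_elongation"]], 1, tolerance = 1e-6)
  expect_equal(sf[["shape_flatness"]], 1, tolerance = 1e-6)
})

test_that("a thin rod matches the eigen-decomposition oracle", {
  rod <- array(FALSE, c(9, 9, 9)); rod[3, 3, 2:6] <- TRUE
  sf <- extract_shape(rod, c(1, 1, 1))
  coords <- which(rod, arr.ind = TRUE) - 1
  ev <- sort(eigen(cov(coords) * (nrow(coords) - 1) / nrow(coords),
                   only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(sf[["shape_major_axis"]], 4 * sqrt(ev[1]))
  expect_equal(sf[["shape_elongation"]], sqrt(ev[2] / ev[1]))
  expect_equal(sf[["shape_elongation"]], 0)
  expect_gt(sf[["shape_major_axis"]], 10 * sf[["shape_least_axis"]] + 1)
})

test_that("shape features are invariant under axis-aligned rotations", {
  m <- mkball(5, 13)
  m[3:5, 2:4, 6:9] <- TRUE  # break the symmetry
  base <- extract_shape(m, c(1, 1, 1))
  rot <- extract_shape(aperm(m, c(2, 3, 1)), c(1, 1, 1))
  expect_equal(base, rot, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("empty masks raise an explicit error", {
  expect_error(extract_shape(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
  expect_error(mesh_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("mesh volume and area respond to spacing correctly", {
  b <- mkball(6, 16)
  iso <- mesh_mask(b, c(1, 1, 1))
  aniso <- mesh_mask(b, c(2, 2, 2))
  expect_equal(aniso$volume / iso$volume, 8, tolerance = 1e-9)
  expect_equal(aniso$area / iso$area, 4, tolerance = 1e-9)
})
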