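test_that("phantom cohorts honour the requested geometry and are deterministic", {
  sp <- phantom_spec(n_patients = 4, n_ln_range = c(1L, 1L), ln_spread = 0,
                     seed = 7)
  co <- generate_cohort(sp)
  expect_length(co, 4L)
  for (v in co) {
    expect_false(any(v$pt_mask & v$ln_mask))
    expect_identical(dim(v$image), dim(v$pt_mask))
    expect_equal(max(label_components_26(v$ln_mask)), 1L)
  }
  expect_identical(generate_cohort(sp), co)
})

test_that("fixed-radius phantoms voxelize to the analytic sphere volume", {
  sp <- phantom_spec(n_patients = 5, pt_radius_range = c(10, 10),
                     n_ln_range = c(1L, 1L), ln_spread = 0, seed = 3)
  co <- generate_cohort(sp)
  va <- 4 / 3 * pi * 10^3
  for (v in co)
    expect_lt(abs(sum(v$pt_mask) * prod(v$spacing) - va) / va, 0.10)
})

test_that("a grid too small for the requested blobs errors explicitly", {
  sp <- phantom_spec(n_patients = 1, grid_shape = c(12L, 12L, 12L),
                     pt_radius_range = c(10, 10), seed = 1)
  expect_error(generate_cohort(sp), "too small")
})

test_that("null outcome model gives exponential baseline times", {
  X <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "f"))
  gt <- ground_truth(baseline_hazard = 0.05, censor_rate = 1e-9)
  y <- simulate_outcomes(X, gt, seed = 5)
  expect_gt(mean(y$lc_event), 0.999)
  ks <- suppressWarnings(ks.test(y$lc_time, "pexp", 0.05))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted positive coefficient shortens survival times", {
  X <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "f"))
  gt <- ground_truth(planted_features = c(f = 2), censor_rate = 1e-9)
  y <- simulate_outcomes(X, gt, seed = 6)
  expect_lt(cor(X[, 1], y$lc_time, method = "spearman"), 0)
})

test_that("LRC is a composite endpoint: every LC failure is an LRC failure", {
  co <- simulate_feature_cohort(n = 200, seed = 8)
  gt <- ground_truth(planted_features = c(pt_f001 = 1),
                     regional_features = c(ln_f001 = 1))
  y <- simulate_outcomes(cbind(co$pt, co$ln), gt, seed = 9)
  expect_true(all(y$lrc_time <= y$lc_time + 1e-12))
  expect_gte(sum(y$lrc_event), sum(y$lc_event))
  expect_true(all(y$lc_event == 0 | y$lrc_event == 1))
})

test_that("missing planted features are reported by name", {
  X <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  gt <- ground_truth(planted_features = c(nope = 1))
  expect_error(simulate_outcomes(X, gt, seed = 1), "nope")
})

test_that("cohorts round-trip through NIfTI with spacing intact", {
  sp <- phantom_spec(n_patients = 2, grid_shape = c(36L, 36L, 30L),
                     pt_radius_range = c(6, 8), ln_radius_range = c(4.5, 5),
                     ln_spread = 10, seed = 11)
  co <- generate_cohort(sp)
  d <- withr::local_tempdir()
  write_cohort(co, outcomes = NULL, dir = d)
  rb <- read_cohort(d)
  expect_identical(rb[[1]]$pt_mask, co[[1]]$pt_mask)
  expect_equal(rb[[2]]$image, co[[2]]$image, tolerance = 1e-6)
  expect_equal(rb[[1]]$spacing, co[[1]]$spacing)
})
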