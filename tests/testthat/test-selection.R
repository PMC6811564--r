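test_that("PCA sizing counts components to 95% explained variance", {
  set.seed(1)
  base <- rnorm(200)
  X1 <- cbind(a = base, b = 2 * base + 5)        # rank-1, noise-free
  expect_equal(pca_feature_count(X1), 1L)
  ## independent equal-variance features need all components
  X5 <- matrix(rnorm(5000 * 5), 5000, 5,
               dimnames = list(NULL, letters[1:5]))
  expect_equal(pca_feature_count(X5), 5L)
  ## rank bound
  X <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(NULL, paste0("f", 1:40)))
  expect_lte(pca_feature_count(X), 5L)
})

test_that("MRMR ranks a perfectly concordant feature first and punishes
           duplicates", {
  set.seed(2)
  n <- 200
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  time <- rexp(n, 0.05 * exp(2 * X[, 3]))
  event <- rep(1L, n)
  r <- mrmr_rank(X, time, event, k = 3)
  expect_equal(r[1], "f3")
  ## a duplicate of the top feature is never picked second
  X2 <- cbind(X, f3dup = X[, 3])
  r2 <- mrmr_rank(X2, time, event, k = 5)
  expect_equal(r2[1], "f3")
  expect_false(r2[2] == "f3dup")
  ## k = p returns a permutation of all features
  r3 <- mrmr_rank(X, time, event, k = 8)
  expect_setequal(r3, colnames(X))
})

test_that("bootstrap selection rates behave at the threshold boundaries", {
  co <- simulate_feature_cohort(n = 80, n_pt = 10, seed = 3)
  gt <- ground_truth(planted_features = c(pt_f001 = 1.5))
  y <- simulate_outcomes(co$pt, gt, seed = 4)
  one <- bootstrap_mrmr(co$pt, y$lc_time, y$lc_event,
                        selection_config(n_bootstrap = 1L, rng_seed = 5))
  expect_true(all(one$rates %in% c(0, 1)))
  ## a vanishing threshold keeps every feature ever picked
  tiny_thr <- bootstrap_mrmr(co$pt, y$lc_time, y$lc_event,
                             selection_config(n_bootstrap = 10L,
                                              selection_rate_threshold = 1e-9,
                                              rng_seed = 5))
  expect_setequal(tiny_thr$selected, names(tiny_thr$rates)[tiny_thr$rates > 0])
  ## identical seeds give identical results
  a <- bootstrap_mrmr(co$pt, y$lc_time, y$lc_event,
                      selection_config(n_bootstrap = 20L, rng_seed = 9))
  b <- bootstrap_mrmr(co$pt, y$lc_time, y$lc_event,
                      selection_config(n_bootstrap = 20L, rng_seed = 9))
  expect_identical(a$rates, b$rates)
  ## raising the threshold never grows the selected set
  sel_at <- function(thr) names(a$rates)[a$rates >= thr]
  expect_true(all(sel_at(0.8) %in% sel_at(0.6)))
  expect_true(all(sel_at(0.6) %in% sel_at(0.4)))
})

test_that("standardization freezes training statistics", {
  set.seed(6)
  X <- matrix(rnorm(50 * 3, 10, 4), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  std <- fit_standardization(X)
  expect_equal(colMeans(std$Z), c(a = 0, b = 0, c = 0), tolerance = 1e-12)
  Xnew <- matrix(rnorm(20 * 3, 12, 4), 20, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  Znew <- apply_standardization(Xnew, std)
  expect_equal(Znew[1, "a"], (Xnew[1, "a"] - std$center["a"]) / std$scale["a"],
               ignore_attr = TRUE)
})
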