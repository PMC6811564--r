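planted_fit <- function(seed = 1, n = 150) {
  co <- simulate_feature_cohort(n = n, n_pt = 20, seed = seed)
  gt <- ground_truth(planted_features = c(pt_f001 = 1.5))
  y <- simulate_outcomes(co$pt, gt, seed = seed + 100)
  list(X = co$pt, y = y)
}

test_that("a planted strong predictor survives the bootstrap LASSO with the
           right sign", {
  d <- planted_fit(seed = 21)
  m <- rad_cox(d$X, d$y$lc_time, d$y$lc_event, endpoint = "LC",
               cfg = lasso_config(n_bootstrap = 30, rng_seed = 7))
  expect_s3_class(m, "rad_cox")
  expect_true(m$success)
  expect_true("pt_f001" %in% m$features)
  expect_gt(coef(m)[["pt_f001"]], 0)
  expect_gte(m$train_cindex, 0.5)
  ## rad score on new patients has the model's orientation
  rs <- predict(m, d$X)
  expect_length(rs, nrow(d$X))
  expect_gt(cor(rs, d$X[, "pt_f001"]), 0)
})

test_that("training fails gracefully when nothing reaches the rate threshold", {
  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("noise", 1:5)))
  y <- simulate_outcomes(X, ground_truth(), seed = 6)
  m <- rad_cox(X, y$lc_time, y$lc_event,
               cfg = lasso_config(n_bootstrap = 20, rng_seed = 8,
                                  selection_rate_threshold = 1,
                                  lambda_rule = "1se"))
  expect_false(m$success)
  expect_null(coef(m))
  expect_error(predict(m, X), "unsuccessful")
  expect_output(print(m), "unsuccessful")
})

test_that("a forced strong covariate is retained while pure noise is
           discarded", {
  set.seed(31)
  co <- simulate_feature_cohort(n = 150, n_pt = 20, seed = 31)
  gt <- ground_truth(planted_features = c(pt_f001 = 1.2, pt_f002 = -1.0))
  y <- simulate_outcomes(cbind(co$pt, co$lnpt), gt, seed = 32)
  rs <- as.numeric(scale(co$pt[, "pt_f001"]) * 1.2 -
                   scale(co$pt[, "pt_f002"]) * 1.0)
  m <- build_mixed_model(rs, co$lnpt, y$lrc_time, y$lrc_event,
                         lasso_config(n_bootstrap = 30, rng_seed = 9,
                                      lambda_rule = "1se"))
  expect_true(m$success)
  expect_identical(m$features, "lc_rad_score")
})

test_that("duplicated candidates are dropped before the fit", {
  d <- planted_fit(seed = 41)
  X <- cbind(d$X[, 1:4], dup = d$X[, "pt_f001"])
  expect_message(
    m <- rad_cox(X, d$y$lc_time, d$y$lc_event,
                 cfg = lasso_config(n_bootstrap = 10, rng_seed = 3)),
    "collinear")
  expect_false("dup" %in% m$candidates[duplicated(m$candidates)])
  expect_false("dup" %in% names(m$selection_rates))
})

test_that("the bootstrap c-index behaves at its analytic anchors", {
  set.seed(51)
  n <- 120
  time <- rexp(n); event <- rep(1L, n)
  perfect <- evaluate_cindex(risk = -time, time = time, event = event,
                             n_boot = 25, seed = 1)
  expect_true(all(perfect$cindex == 1))
  constant <- evaluate_cindex(risk = rep(2, n), time = time, event = event,
                              n_boot = 10, seed = 2)
  expect_true(all(constant$cindex == 0.5))
  ## antisymmetry on tie-free data
  r <- rnorm(n)
  expect_equal(harrell_cindex(time, event, r) +
               harrell_cindex(time, event, -r), 1, tolerance = 1e-12)
})

test_that("paired Wilcoxon comparison: identity, constant shift, ordering", {
  set.seed(61)
  a <- runif(100, 0.5, 0.7)
  expect_equal(compare_models(a, a), 1)
  p_shift <- compare_models(a, a + 0.05)
  ## the signed-rank statistic only sees signs and ranks, so any
  ## all-positive constant shift attains the same (minimal) p-value
  expect_equal(p_shift, compare_models(a, a + 0.2), tolerance = 1e-12)
  mixed <- a + 0.05 * rep(c(1, -1), 50)
  expect_gt(compare_models(a, mixed), p_shift)
})

test_that("landmark stratification fits and freezes a Youden threshold", {
  set.seed(71)
  n <- 200
  risk <- rnorm(n)
  ## construct outcomes perfectly separated at risk = 0
  time <- ifelse(risk > 0, runif(n, 2, 16), runif(n, 30, 60))
  event <- as.integer(risk > 0)
  st <- stratify_risk(risk, time, event)
  expect_equal(st$youden, 1)
  expect_true(st$threshold > max(risk[risk <= 0]) &
              st$threshold < min(risk[risk > 0]))
  expect_true(st$stratified)
  expect_lt(st$logrank_p, 1e-10)
  ## frozen threshold applied to a validation set from the same law
  risk_v <- rnorm(80)
  time_v <- ifelse(risk_v > 0, runif(80, 2, 16), runif(80, 30, 60))
  stv <- stratify_risk(risk, time, event, risk = risk_v, time = time_v,
                       event = as.integer(risk_v > 0))
  expect_lt(stv$logrank_p, 1e-6)
})

test_that("model summaries and serialization helpers are coherent", {
  d <- planted_fit(seed = 81)
  m <- rad_cox(d$X, d$y$lc_time, d$y$lc_event,
               cfg = lasso_config(n_bootstrap = 15, rng_seed = 2))
  s <- summary(m)
  expect_s3_class(s, "summary.rad_cox")
  expect_output(print(s), "Selection rates")
  expect_equal(sort(names(coef(m))), sort(m$features))
})
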