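## Bootstrap LASSO-Cox model building with the 60% selection-rate rule,
## the rad-score linear predictor, bootstrap c-index evaluation, paired
## Wilcoxon model comparison and landmark risk stratification.

#' LASSO-Cox configuration
#'
#' @param n_bootstrap Bootstrap resamples for the selection rate
#'   (the reference procedure uses 100).
#' @param cv_folds Folds for the cross-validated penalty (default 5).
#' @param selection_rate_threshold Fraction of resamples in which a
#'   feature must carry a nonzero coefficient (default 0.60).
#' @param lambda_rule `"min"` (penalty at minimum CV deviance) or
#'   `"1se"`.
#' @param rng_seed Integer seed.
#' @return An object of class `lasso_config`.
#' @export
lasso_config <- function(n_bootstrap = 100L, cv_folds = 5L,
                         selection_rate_threshold = 0.60,
                         lambda_rule = c("min", "1se"), rng_seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  if (cv_folds < 2L) stopf("cv_folds must be >= 2")
  if (selection_rate_threshold <= 0 || selection_rate_threshold > 1)
    stopf("selection_rate_threshold must be in (0, 1]")
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 cv_folds = as.integer(cv_folds),
                 selection_rate_threshold = selection_rate_threshold,
                 lambda_rule = lambda_rule, rng_seed = as.integer(rng_seed)),
            class = "lasso_config")
}

## Drop candidates perfectly rank-correlated with an earlier candidate.
drop_collinear <- function(X) {
  if (ncol(X) < 2L) return(X)
  rho <- abs(suppressWarnings(stats::cor(X, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  drop <- logical(ncol(X))
  for (j in 2:ncol(X))
    if (any(rho[j, 1:(j - 1)][!drop[1:(j - 1)]] >= 1 - 1e-12)) drop[j] <- TRUE
  if (any(drop))
    message("dropping perfectly collinear candidate(s): ",
            paste(colnames(X)[drop], collapse = ", "))
  X[, !drop, drop = FALSE]
}

#' Bootstrap LASSO-Cox feature selection rates
#'
#' Per bootstrap resample, fits an L1-penalized Cox path with the penalty
#' chosen by cross-validated partial likelihood and records which
#' features keep nonzero coefficients; the final set is the features
#' reaching the selection-rate threshold.
#'
#' @param X Numeric matrix (already standardized and restricted to the
#'   MRMR-selected candidates plus any forced covariates).
#' @param time,event Survival endpoint.
#' @param cfg A [lasso_config()].
#' @return List with `rates` (named numeric) and `selected`.
#' @export
bootstrap_lasso_cox <- function(X, time, event, cfg = lasso_config()) {
  X <- drop_collinear(X)
  n <- nrow(X)
  p <- ncol(X)
  set.seed(cfg$rng_seed)
  hits <- stats::setNames(numeric(p), colnames(X))
  done <- 0L; attempts <- 0L
  while (done < cfg$n_bootstrap) {
    attempts <- attempts + 1L
    if (attempts > 20L * cfg$n_bootstrap)
      stopf("bootstrap LASSO keeps failing (too few events?)")
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(event[idx]) < cfg$cv_folds) next
    nz <- tryCatch({
      if (p == 1L) {
        ## the penalized path needs >= 2 columns; use the univariate
        ## Cox Wald test as the per-resample inclusion rule
        fit <- survival::coxph(survival::Surv(time[idx], event[idx]) ~ .,
                               data = as.data.frame(X[idx, , drop = FALSE]))
        pv <- summary(fit)$coefficients[1, "Pr(>|z|)"]
        if (is.finite(pv) && pv < 0.05) colnames(X) else character(0)
      } else {
        cvf <- glmnet::cv.glmnet(X[idx, , drop = FALSE],
                                 survival::Surv(time[idx], event[idx]),
                                 family = "cox", nfolds = cfg$cv_folds)
        lam <- if (cfg$lambda_rule == "min") cvf$lambda.min else cvf$lambda.1se
        cf <- as.matrix(stats::coef(cvf, s = lam))
        rownames(cf)[cf[, 1] != 0]
      }
    }, error = function(e) NULL)
    if (is.null(nz)) next
    hits[nz] <- hits[nz] + 1
    done <- done + 1L
  }
  rates <- hits / cfg$n_bootstrap
  list(rates = rates,
       selected = names(rates)[rates >= cfg$selection_rate_threshold])
}

#' Fit a radiomic Cox model (bootstrap LASSO selection + unpenalized
#' refit)
#'
#' The central model constructor: standardizes the candidate matrix
#' (training statistics are frozen in the object), runs
#' [bootstrap_lasso_cox()], refits an unpenalized multivariate Cox model
#' on the surviving features, and stores the rad-score definition (the
#' Cox linear predictor). Training with an empty surviving set is
#' reported as unsuccessful rather than an error, mirroring how candidate
#' groups can be discarded wholesale in the selection.
#'
#' @param X Numeric candidate matrix (patients x features, named
#'   columns).
#' @param time,event Survival endpoint of the training cohort.
#' @param endpoint Label, e.g. `"LC"` or `"LRC"`.
#' @param cfg A [lasso_config()].
#' @param standardize Standardize `X` with training statistics (set to
#'   `FALSE` if `X` is already on a frozen scale).
#' @return An object of class `rad_cox`; check `$success`. Fields
#'   include `features`, `coefficients`, `selection_rates`, `std`
#'   (frozen standardization), `cox_fit`, `train_cindex`.
#' @export
rad_cox <- function(X, time, event, endpoint = "LRC",
                    cfg = lasso_config(), standardize = TRUE) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  std <- if (standardize) fit_standardization(X) else
    list(center = stats::setNames(rep(0, ncol(X)), colnames(X)),
         scale = stats::setNames(rep(1, ncol(X)), colnames(X)), Z = X)
  Z <- std$Z
  sel <- bootstrap_lasso_cox(Z, time, event, cfg)
  obj <- structure(list(endpoint = endpoint, success = FALSE,
                        candidates = colnames(X),
                        selection_rates = sel$rates,
                        features = sel$selected,
                        coefficients = NULL, std = std[c("center", "scale")],
                        cox_fit = NULL, train_cindex = NA_real_,
                        threshold = NULL, cfg = cfg),
                   class = "rad_cox")
  if (!length(sel$selected)) return(obj)
  df <- as.data.frame(Z[, sel$selected, drop = FALSE])
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df)
  obj$success <- TRUE
  obj$coefficients <- stats::coef(fit)
  names(obj$coefficients) <- sel$selected
  obj$cox_fit <- fit
  obj$train_cindex <- as.numeric(survival::concordance(fit)$concordance)
  obj
}

#' @export
print.rad_cox <- function(x, ...) {
  cat(sprintf("Radiomic Cox model (endpoint %s)\n", x$endpoint))
  if (!x$success) {
    cat("  training unsuccessful: no feature reached the selection-rate threshold\n")
    return(invisible(x))
  }
  cat(sprintf("  %d feature(s), training c-index %.3f\n",
              length(x$features), x$train_cindex))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.rad_cox <- function(object, ...) object$coefficients

#' @export
summary.rad_cox <- function(object, ...) {
  out <- list(endpoint = object$endpoint, success = object$success,
              selection_rates = sort(object$selection_rates,
                                     decreasing = TRUE),
              coefficients = object$coefficients,
              train_cindex = object$train_cindex,
              cox_summary = if (object$success) summary(object$cox_fit))
  class(out) <- "summary.rad_cox"
  out
}

#' @export
print.summary.rad_cox <- function(x, ...) {
  cat(sprintf("Radiomic Cox model, endpoint %s (%s)\n", x$endpoint,
              if (x$success) "trained" else "training unsuccessful"))
  cat("Selection rates:\n")
  print(round(x$selection_rates, 3))
  if (x$success) {
    cat(sprintf("Training c-index: %.3f\n", x$train_cindex))
    print(x$cox_summary$coefficients)
  }
  invisible(x)
}

#' Rad score (Cox linear predictor) for new patients
#'
#' @param object A fitted [rad_cox()] model.
#' @param newdata Numeric matrix containing at least the model's feature
#'   columns, on the original (unstandardized) scale unless the model was
#'   fit with `standardize = FALSE`.
#' @param ... Unused.
#' @return Numeric vector of rad scores.
#' @export
predict.rad_cox <- function(object, newdata, ...) {
  if (!object$success) stopf("model training was unsuccessful; no rad score")
  feats <- object$features
  missing <- setdiff(feats, colnames(newdata))
  if (length(missing))
    stopf("newdata lacks model feature(s): %s", paste(missing, collapse = ", "))
  Z <- scale(newdata[, feats, drop = FALSE],
             center = object$std$center[feats],
             scale = object$std$scale[feats])
  as.numeric(Z %*% object$coefficients)
}

#' Harrell concordance index of a risk score
#'
#' Higher score = higher risk; tied scores count 0.5.
#'
#' @param time,event Survival outcome.
#' @param risk Numeric risk score.
#' @return Concordance in \[0, 1\] (NA if no comparable pairs).
#' @export
harrell_cindex <- function(time, event, risk) {
  if (stats::sd(risk) == 0) return(0.5)
  cc <- tryCatch(
    survival::concordance(survival::Surv(time, event) ~ risk, reverse = TRUE),
    error = function(e) NULL)
  if (is.null(cc) || (cc$count["concordant"] + cc$count["discordant"] +
                      cc$count["tied.x"]) == 0) return(NA_real_)
  as.numeric(cc$concordance)
}

#' Bootstrap c-index distribution of a model on a validation cohort
#'
#' Harrell's c-index of the rad score on `n_boot` bootstrap resamples of
#' the validation cohort; resamples without comparable pairs are redrawn.
#'
#' @param model A fitted [rad_cox()] (or any object usable with
#'   [predict.rad_cox()]); alternatively pass precomputed scores via
#'   `risk`.
#' @param X_val Validation feature matrix (original scale).
#' @param time,event Validation outcomes.
#' @param n_boot Number of resamples (default 100).
#' @param seed Integer seed; use the same seed across models to obtain
#'   paired distributions on shared resamples.
#' @param risk Optional precomputed risk scores (overrides `model`).
#' @return List with `cindex` (length `n_boot`), `mean`, `ci` (2.5 and
#'   97.5 percentiles).
#' @export
evaluate_cindex <- function(model = NULL, X_val = NULL, time, event,
                            n_boot = 100L, seed = 1L, risk = NULL) {
  if (is.null(risk)) risk <- predict(model, X_val)
  n <- length(time)
  set.seed(seed)
  out <- numeric(n_boot)
  b <- 0L; attempts <- 0L
  while (b < n_boot) {
    attempts <- attempts + 1L
    if (attempts > 50L * n_boot) stopf("no comparable pairs in resamples")
    idx <- sample.int(n, n, replace = TRUE)
    cc <- harrell_cindex(time[idx], event[idx], risk[idx])
    if (is.na(cc)) next
    b <- b + 1L
    out[b] <- cc
  }
  list(cindex = out, mean = mean(out),
       ci = stats::quantile(out, c(0.025, 0.975), names = FALSE))
}

#' Paired Wilcoxon comparison of two bootstrap c-index distributions
#'
#' @param a,b Equal-length c-index vectors computed on shared resamples.
#' @return Two-sided signed-rank p-value (1 if all differences are zero).
#' @export
compare_models <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- b - a
  if (all(d == 0)) return(1)
  stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
}

#' Landmark risk stratification by the rad score
#'
#' Fits the score threshold maximizing Youden's J for failure by
#' `horizon` months on the training cohort (patients censored event-free
#' before the horizon are excluded from threshold fitting), then splits a
#' target cohort at that threshold and tests the groups with a two-sided
#' log-rank test.
#'
#' @param train_risk,train_time,train_event Training scores and outcomes
#'   used to fit the threshold.
#' @param risk,time,event Target-cohort scores and outcomes (default:
#'   the training cohort itself).
#' @param horizon Landmark in months (default 18).
#' @return List: `threshold`, `groups` (factor high/low), `logrank_p`,
#'   `youden`, `stratified` (FALSE when one group is empty), `km`
#'   (survfit object, NULL if not stratified).
#' @export
stratify_risk <- function(train_risk, train_time, train_event,
                          risk = train_risk, time = train_time,
                          event = train_event, horizon = 18) {
  if (horizon <= 0) stopf("horizon must be > 0")
  case <- train_event == 1 & train_time <= horizon
  ctrl <- train_time > horizon
  use <- case | ctrl
  if (!any(case[use]) || !any(ctrl[use]))
    stopf("landmark classes degenerate: cannot fit a threshold")
  r <- train_risk[use]; y <- case[use]
  cuts <- sort(unique(r))
  cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
  if (!length(cuts)) cuts <- stats::median(r)
  jj <- vapply(cuts, function(cu) {
    sens <- mean(r[y] > cu); spec <- mean(r[!y] <= cu)
    sens + spec - 1
  }, 0)
  thr <- cuts[which.max(jj)]
  grp <- factor(ifelse(risk > thr, "high", "low"), levels = c("low", "high"))
  if (any(table(grp) == 0))
    return(list(threshold = thr, groups = grp, logrank_p = NA_real_,
                youden = max(jj), stratified = FALSE, km = NULL))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  km <- survival::survfit(survival::Surv(time, event) ~ grp)
  list(threshold = thr, groups = grp, logrank_p = as.numeric(p),
       youden = max(jj), stratified = TRUE, km = km)
}

#' Kaplan-Meier plot of the stratified risk groups
#'
#' @param strat Result of [stratify_risk()].
#' @param main Plot title.
#' @return Invisibly, the survfit object.
#' @export
plot_risk_groups <- function(strat, main = "Risk-group control rate") {
  if (!isTRUE(strat$stratified)) stopf("stratification failed; nothing to plot")
  graphics::plot(strat$km, col = c("forestgreen", "firebrick"), lwd = 2,
                 xlab = "Time [months]", ylab = "Control rate", main = main)
  graphics::legend("bottomleft", c("low risk", "high risk"),
                   col = c("forestgreen", "firebrick"), lwd = 2, bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", strat$logrank_p), side = 3,
                  line = 0, cex = 0.8)
  invisible(strat$km)
}

#' Build the LC rad-score model from PT features
#'
#' Convenience wrapper: [rad_cox()] on the MRMR-selected PT features
#' against the local-control endpoint.
#'
#' @param X_pt PT feature matrix restricted to the selected features.
#' @param time,event LC endpoint.
#' @param cfg A [lasso_config()].
#' @return A `rad_cox` object with endpoint `"LC"`.
#' @export
build_lc_rad_score <- function(X_pt, time, event, cfg = lasso_config()) {
  rad_cox(X_pt, time, event, endpoint = "LC", cfg = cfg)
}

#' Build the mixed PT + LN model
#'
#' Candidate matrix = LC rad score column plus the MRMR-selected LN (or
#' LNPT) features; the rad score is treated as an ordinary covariate in
#' the bootstrap LASSO.
#'
#' @param rad_score Per-patient LC rad score (training cohort).
#' @param X_extra Matrix of selected LN / LNPT features (or N stage).
#' @param time,event LRC endpoint.
#' @param cfg A [lasso_config()].
#' @return A `rad_cox` object with endpoint `"LRC"`. `$success` is FALSE
#'   when nothing survives; the model reduces to PT-only information when
#'   only the rad score survives.
#' @export
build_mixed_model <- function(rad_score, X_extra, time, event,
                              cfg = lasso_config()) {
  X <- cbind(lc_rad_score = rad_score, X_extra)
  rad_cox(X, time, event, endpoint = "LRC", cfg = cfg)
}
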