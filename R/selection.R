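## Bootstrap MRMR preselection: feature count sized by PCA at 95%
## explained variance, greedy maximum-relevance minimum-redundancy
## ranking with Spearman redundancy, and the 60% selection-rate rule.

#' Selection configuration
#'
#' @param n_bootstrap Number of bootstrap resamples (the reference
#'   procedure uses 1000).
#' @param selection_rate_threshold Minimum fraction of resamples in which
#'   a feature must be ranked to enter the final set (default 0.60).
#' @param variance_explained Cumulative explained-variance level that
#'   sizes the MRMR feature count via PCA (default 0.95).
#' @param relevance_metric `"cindex"` (|univariate concordance - 0.5|) or
#'   `"cox_z"` (absolute univariate Cox Wald z).
#' @param rng_seed Integer seed.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_bootstrap = 1000L,
                             selection_rate_threshold = 0.60,
                             variance_explained = 0.95,
                             relevance_metric = c("cindex", "cox_z"),
                             rng_seed = 1L) {
  relevance_metric <- match.arg(relevance_metric)
  if (selection_rate_threshold < 0 || selection_rate_threshold > 1)
    stopf("selection_rate_threshold must be in [0, 1]")
  if (variance_explained <= 0 || variance_explained >= 1)
    stopf("variance_explained must be in (0, 1)")
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 selection_rate_threshold = selection_rate_threshold,
                 variance_explained = variance_explained,
                 relevance_metric = relevance_metric,
                 rng_seed = as.integer(rng_seed)),
            class = "selection_config")
}

#' Freeze a z-score standardization on training data
#'
#' @param X Numeric matrix (patients x features).
#' @return List with `center`, `scale` and the transformed matrix `Z`;
#'   apply to new data with [apply_standardization()].
#' @export
fit_standardization <- function(X) {
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  list(center = center, scale = scale_,
       Z = scale(X, center = center, scale = scale_)[, , drop = FALSE])
}

#' @rdname fit_standardization
#' @param std A standardization from [fit_standardization()].
#' @export
apply_standardization <- function(X, std) {
  scale(X[, names(std$center), drop = FALSE],
        center = std$center, scale = std$scale)[, , drop = FALSE]
}

#' Feature count from PCA explained variance
#'
#' Smallest number of principal components of the z-scored matrix whose
#' cumulative explained variance reaches the configured level. Constant
#' columns are dropped before the PCA.
#'
#' @param X Numeric matrix (>= 2 rows and columns).
#' @param cfg A [selection_config()].
#' @return Integer component count.
#' @export
pca_feature_count <- function(X, cfg = selection_config()) {
  if (nrow(X) < 2L || ncol(X) < 2L)
    stopf("PCA sizing needs at least 2 samples and 2 features")
  keep <- apply(X, 2, function(x) stats::sd(x) > 0)
  X <- X[, keep, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  as.integer(which(cumsum(ve) >= cfg$variance_explained)[1])
}

## Relevance of each feature column for a survival endpoint.
relevance_scores <- function(X, time, event, metric = "cindex") {
  srv <- survival::Surv(time, event)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (stats::sd(x) == 0) return(0)
    if (metric == "cindex") {
      cc <- tryCatch(
        survival::concordance(srv ~ x)$concordance,
        error = function(e) 0.5)
      abs(cc - 0.5)
    } else {
      z <- tryCatch({
        fit <- survival::coxph(srv ~ x)
        abs(summary(fit)$coefficients[1, "z"])
      }, error = function(e) 0)
      if (is.finite(z)) z else 0
    }
  }, 0)
}

#' Greedy MRMR ranking of features against a survival endpoint
#'
#' Forward selection of `k` features maximizing
#' relevance - mean redundancy, where relevance is the absolute
#' displacement of the univariate concordance index from 0.5 and
#' redundancy is the mean absolute Spearman correlation with the already
#' selected set. Ties are broken by feature name.
#'
#' @param X Numeric matrix with column names.
#' @param time,event Survival endpoint (times and 0/1 indicators).
#' @param k Number of features to rank.
#' @param cfg A [selection_config()].
#' @return Character vector of k feature names in selection order.
#' @export
mrmr_rank <- function(X, time, event, k, cfg = selection_config()) {
  p <- ncol(X)
  if (k > p) stopf("k = %d exceeds the %d available features", k, p)
  nm <- colnames(X)
  rel <- relevance_scores(X, time, event, cfg$relevance_metric)
  rho <- abs(suppressWarnings(stats::cor(X, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  ord <- order(-rel, nm)  # max relevance, lexicographic tie-break
  sel <- integer(0)
  avail <- setdiff(seq_len(p), ord[1])
  sel <- ord[1]
  while (length(sel) < k) {
    red <- if (length(sel) == 1L) rho[avail, sel]
           else rowMeans(rho[avail, sel, drop = FALSE])
    score <- rel[avail] - red
    pick <- avail[order(-score, nm[avail])[1]]
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  nm[sel]
}

#' Bootstrap MRMR selection with the 60% rule
#'
#' Runs [mrmr_rank()] on `n_bootstrap` bootstrap resamples (full-size,
#' with replacement; resamples without any event are redrawn) with a
#' fixed per-run feature count `k` (PCA-sized on the full training matrix
#' unless given) and keeps the features ranked in at least the threshold
#' fraction of runs.
#'
#' @param X Numeric matrix with column names.
#' @param time,event Survival endpoint.
#' @param cfg A [selection_config()].
#' @param k Features per run; default [pca_feature_count()] of `X`.
#' @param group Optional label stored in the result.
#' @return An object of class `selection_result`: `k`, `rates` (named),
#'   `selected`, `group`, `n_bootstrap`.
#' @export
bootstrap_mrmr <- function(X, time, event, cfg = selection_config(),
                           k = NULL, group = NA_character_) {
  if (is.null(k)) k <- min(pca_feature_count(X, cfg), ncol(X))
  n <- nrow(X)
  set.seed(cfg$rng_seed)
  hits <- stats::setNames(numeric(ncol(X)), colnames(X))
  redraws <- 0L
  for (b in seq_len(cfg$n_bootstrap)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(event[idx]) > 0) break
      redraws <- redraws + 1L
      if (redraws > 100L * cfg$n_bootstrap)
        stopf("bootstrap resampling keeps drawing event-free samples")
    }
    picked <- mrmr_rank(X[idx, , drop = FALSE], time[idx], event[idx], k, cfg)
    hits[picked] <- hits[picked] + 1
  }
  rates <- hits / cfg$n_bootstrap
  structure(list(k = k, rates = rates,
                 selected = names(rates)[rates >= cfg$selection_rate_threshold],
                 group = group, n_bootstrap = cfg$n_bootstrap,
                 threshold = cfg$selection_rate_threshold,
                 event_redraws = redraws),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Bootstrap MRMR selection (%s): k = %d, %d resamples\n",
              x$group %||% "?", x$k, x$n_bootstrap))
  cat(sprintf("  %d / %d features at rate >= %.2f: %s\n",
              length(x$selected), length(x$rates), x$threshold,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
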