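## End-to-end orchestration: synthesize or load a cohort, preprocess,
## extract PT / LN / LNPT features, preselect, fit the model variants
## (LC rad score, PT model, mixed PT+LN, mixed PT+LNPT, PT + N stage),
## evaluate on the validation split and stratify risk groups.

#' Pipeline configuration
#'
#' @param out_dir Run directory for all outputs.
#' @param seed Global seed; per-stage seeds are derived from it
#'   deterministically, so stages can be rerun independently.
#' @param phantom A [phantom_spec()] to synthesize a cohort, or `NULL`
#'   when `cohort_dir` or `features` is given.
#' @param cohort_dir Directory with a cohort written by [write_cohort()].
#' @param truth A [ground_truth()] used to simulate outcomes from the
#'   extracted features (planted names must exist in the panel), or
#'   `NULL` when `clinical` supplies outcomes.
#' @param clinical Optional `survival_table` with outcomes and N stage.
#' @param features Optional precomputed list of matrices `pt`, `ln`,
#'   `lnpt` (skips synthesis, preprocessing and extraction).
#' @param preprocess A [preprocess_config()].
#' @param selection A [selection_config()].
#' @param lasso A [lasso_config()].
#' @param train_fraction Fraction of patients assigned to the training
#'   cohort (the rest validate).
#' @param n_eval_boot Bootstrap resamples for validation c-index
#'   distributions (shared across models for pairing).
#' @param horizon Stratification landmark in months.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("lnradiomics_run_"),
                            seed = 1L,
                            phantom = NULL, cohort_dir = NULL,
                            truth = NULL, clinical = NULL, features = NULL,
                            preprocess = preprocess_config(),
                            selection = selection_config(),
                            lasso = lasso_config(),
                            train_fraction = 0.6,
                            n_eval_boot = 100L, horizon = 18) {
  if (is.null(phantom) && is.null(cohort_dir) && is.null(features))
    stopf("one of phantom, cohort_dir or features must be given")
  if (is.null(truth) && is.null(clinical))
    stopf("either truth (to simulate outcomes) or clinical must be given")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 phantom = phantom, cohort_dir = cohort_dir, truth = truth,
                 clinical = clinical, features = features,
                 preprocess = preprocess, selection = selection,
                 lasso = lasso, train_fraction = train_fraction,
                 n_eval_boot = as.integer(n_eval_boot), horizon = horizon),
            class = "pipeline_config")
}

#' Validate cohort inputs without running the pipeline
#'
#' Checks image/mask geometry agreement, clinical-table completeness and
#' composite-endpoint consistency (a loco-regional failure can never
#' occur after the local failure of the same patient).
#'
#' @param cohort List of `volume_with_masks` (or `NULL`).
#' @param clinical A `survival_table` data.frame (or `NULL`).
#' @return Data.frame with columns `patient_id`, `problem`; zero rows
#'   when everything is consistent.
#' @export
validate_inputs <- function(cohort = NULL, clinical = NULL) {
  problems <- list()
  add <- function(id, msg) problems[[length(problems) + 1L]] <<-
    data.frame(patient_id = id, problem = msg, stringsAsFactors = FALSE)
  for (v in cohort %||% list()) {
    if (is.null(v$image)) { add(v$patient_id, "missing image"); next }
    if (is.null(v$pt_mask) || is.null(v$ln_mask)) {
      add(v$patient_id, "missing mask"); next
    }
    if (!identical(dim(v$image), dim(v$pt_mask)) ||
        !identical(dim(v$image), dim(v$ln_mask)))
      add(v$patient_id, "image and mask grids disagree")
    if (any(v$spacing <= 0)) add(v$patient_id, "non-positive voxel spacing")
    if (!any(v$pt_mask)) add(v$patient_id, "empty PT mask")
    if (!any(v$ln_mask)) add(v$patient_id, "empty LN mask")
  }
  if (!is.null(clinical)) {
    need <- c("patient_id", "lc_time", "lc_event", "lrc_time", "lrc_event")
    miss <- setdiff(need, names(clinical))
    if (length(miss))
      add("<table>", paste("clinical table lacks columns:",
                           paste(miss, collapse = ", ")))
    else {
      bad <- clinical$lrc_time > clinical$lc_time + 1e-9
      for (id in clinical$patient_id[bad])
        add(id, "inconsistent composite endpoint: LRC time after LC time")
      bad2 <- clinical$lc_event == 1 & clinical$lrc_event == 0
      for (id in clinical$patient_id[bad2])
        add(id, "inconsistent composite endpoint: LC failure without LRC failure")
      if ("n_stage" %in% names(clinical)) {
        badn <- !(clinical$n_stage %in% 1:5)
        for (id in clinical$patient_id[badn])
          add(id, "invalid N stage (expected ordinal 1..5)")
      }
    }
  }
  if (!length(problems))
    return(data.frame(patient_id = character(0), problem = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, problems)
}

write_model_json <- function(model, path) {
  out <- list(endpoint = model$endpoint, success = model$success,
              features = model$features,
              coefficients = as.list(model$coefficients),
              selection_rates = as.list(model$selection_rates),
              standardization = list(center = as.list(model$std$center),
                                     scale = as.list(model$std$scale)),
              train_cindex = model$train_cindex)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the workflow end to end: cohort synthesis or loading,
#' preprocessing with the artifact eligibility rule, extraction of the
#' 285-feature PT and LN panels and the 14 LNPT features, per-group
#' bootstrap MRMR preselection, model building (LC rad score, PT model,
#' mixed PT+LN, mixed PT+LNPT, PT + N stage), paired bootstrap c-index
#' evaluation on the validation split, and 18-month risk stratification.
#' All numeric outputs are written under `cfg$out_dir` and returned.
#'
#' @param cfg A [pipeline_config()].
#' @return List with elements `features`, `outcomes`, `split`,
#'   `selection`, `models`, `evaluation`, `stratification`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }

  ## --- stage 1: features -------------------------------------------------
  if (!is.null(cfg$features)) {
    feats <- cfg$features
    logf("using %d precomputed feature rows", nrow(feats$pt))
    eligibility <- NULL
  } else {
    cohort <- if (!is.null(cfg$phantom)) {
      ph <- cfg$phantom
      ph$seed <- stage_seed(cfg$seed, "synth") + ph$seed
      logf("synthesizing %d phantom patients", ph$n_patients)
      generate_cohort(ph)
    } else {
      logf("reading cohort from %s", cfg$cohort_dir)
      read_cohort(cfg$cohort_dir)
    }
    probs <- validate_inputs(cohort)
    if (nrow(probs))
      stopf("input validation failed for %s: %s",
            probs$patient_id[1], probs$problem[1])
    pre <- lapply(cohort, function(v) {
      out <- preprocess_patient(v, cfg$preprocess)
      logf("preprocess %s: eligible=%s artifact_fraction=%.2f",
           v$patient_id, out$eligible, out$artifact_fraction)
      out
    })
    eligibility <- data.frame(
      patient_id = vapply(pre, `[[`, "", "patient_id"),
      eligible = vapply(pre, `[[`, NA, "eligible"),
      artifact_fraction = vapply(pre, `[[`, 0, "artifact_fraction"))
    utils::write.csv(eligibility, file.path(cfg$out_dir, "eligibility.csv"),
                     row.names = FALSE)
    pre <- Filter(function(v) isTRUE(v$eligible), pre)
    if (length(pre) < 10L)
      stopf("stage extract: only %d eligible patients", length(pre))
    logf("extracting features for %d eligible patients", length(pre))
    feats <- extract_cohort(pre)
  }
  for (g in names(feats))
    utils::write.csv(feats[[g]],
                     file.path(cfg$out_dir, sprintf("features_%s.csv", g)))

  ## --- stage 2: outcomes -------------------------------------------------
  outcomes <- if (!is.null(cfg$clinical)) cfg$clinical else {
    all_feats <- cbind(feats$pt,
                       `colnames<-`(feats$ln, paste0("ln__", colnames(feats$ln))),
                       `colnames<-`(feats$lnpt, paste0("lnpt__", colnames(feats$lnpt))))
    simulate_outcomes(all_feats, cfg$truth,
                      seed = stage_seed(cfg$seed, "outcomes"))
  }
  outcomes <- outcomes[match(rownames(feats$pt), outcomes$patient_id), ]
  if (any(is.na(outcomes$lc_time)))
    stopf("stage outcomes: clinical table misses patients present in features")
  utils::write.csv(outcomes, file.path(cfg$out_dir, "clinical_used.csv"),
                   row.names = FALSE)

  ## --- stage 3: train / validation split ---------------------------------
  n <- nrow(feats$pt)
  set.seed(stage_seed(cfg$seed, "split"))
  train_idx <- sort(sample.int(n, round(cfg$train_fraction * n)))
  val_idx <- setdiff(seq_len(n), train_idx)
  logf("split: %d training / %d validation", length(train_idx), length(val_idx))
  tr <- function(m) m[train_idx, , drop = FALSE]
  va <- function(m) m[val_idx, , drop = FALSE]
  y_tr <- outcomes[train_idx, ]; y_va <- outcomes[val_idx, ]

  ## --- stage 4: MRMR preselection per group ------------------------------
  sel_cfg <- cfg$selection
  sel_cfg$rng_seed <- stage_seed(cfg$seed, "mrmr")
  run_sel <- function(X, time, event, group) {
    s <- bootstrap_mrmr(X, time, event, sel_cfg, group = group)
    logf("MRMR %s: k=%d, %d selected", group, s$k, length(s$selected))
    s
  }
  selection <- list(
    pt_lc = run_sel(tr(feats$pt), y_tr$lc_time, y_tr$lc_event, "PT~LC"),
    pt_lrc = run_sel(tr(feats$pt), y_tr$lrc_time, y_tr$lrc_event, "PT~LRC"),
    ln_lrc = run_sel(tr(feats$ln), y_tr$lrc_time, y_tr$lrc_event, "LN~LRC"),
    lnpt_lrc = run_sel(tr(feats$lnpt), y_tr$lrc_time, y_tr$lrc_event,
                       "LNPT~LRC"))
  rates <- do.call(rbind, lapply(names(selection), function(nm) {
    s <- selection[[nm]]
    data.frame(group = s$group, feature = names(s$rates),
               rate = as.numeric(s$rates),
               selected = names(s$rates) %in% s$selected)
  }))
  utils::write.csv(rates, file.path(cfg$out_dir, "selection_rates.csv"),
                   row.names = FALSE)

  ## --- stage 5: models ---------------------------------------------------
  las <- cfg$lasso
  las$rng_seed <- stage_seed(cfg$seed, "lasso")
  models <- list()
  sel_or_fail <- function(s) {
    if (!length(s$selected)) NULL else s$selected
  }
  ## LC rad score (PT features vs local control)
  pt_lc_feats <- sel_or_fail(selection$pt_lc)
  models$lc_rad_score <- if (is.null(pt_lc_feats)) {
    logf("LC rad score: no MRMR-selected features; training unsuccessful")
    NULL
  } else build_lc_rad_score(tr(feats$pt)[, pt_lc_feats, drop = FALSE],
                            y_tr$lc_time, y_tr$lc_event, las)
  ## PT model (PT features vs LRC directly)
  pt_lrc_feats <- sel_or_fail(selection$pt_lrc)
  models$pt_model <- if (is.null(pt_lrc_feats)) NULL else
    rad_cox(tr(feats$pt)[, pt_lrc_feats, drop = FALSE],
            y_tr$lrc_time, y_tr$lrc_event, endpoint = "LRC", cfg = las)
  ## mixed models need the rad score
  have_rs <- !is.null(models$lc_rad_score) && models$lc_rad_score$success
  rs_tr <- if (have_rs) predict(models$lc_rad_score, tr(feats$pt))
  mixed_of <- function(sel_res, X) {
    if (!have_rs) return(NULL)
    extra <- sel_or_fail(sel_res)
    Xc <- if (is.null(extra)) {
      matrix(numeric(0), nrow = length(train_idx), ncol = 0,
             dimnames = list(NULL, character(0)))
    } else tr(X)[, extra, drop = FALSE]
    build_mixed_model(rs_tr, Xc, y_tr$lrc_time, y_tr$lrc_event, las)
  }
  models$mixed_ln <- mixed_of(selection$ln_lrc, feats$ln)
  models$mixed_lnpt <- mixed_of(selection$lnpt_lrc, feats$lnpt)
  ## N-stage comparison model: rad score + ordinal N stage
  models$nstage <- if (have_rs) {
    Xn <- cbind(n_stage = as.numeric(y_tr$n_stage))
    build_mixed_model(rs_tr, Xn, y_tr$lrc_time, y_tr$lrc_event, las)
  }
  for (nm in names(models)) {
    m <- models[[nm]]
    if (is.null(m)) next
    write_model_json(m, file.path(cfg$out_dir, sprintf("model_%s.json", nm)))
    logf("model %s: %s", nm,
         if (m$success) sprintf("%d feature(s), train c-index %.3f",
                                length(m$features), m$train_cindex)
         else "training unsuccessful")
  }

  ## --- stage 6: validation evaluation (shared resamples) ------------------
  eval_seed <- stage_seed(cfg$seed, "evaluate")
  val_X <- function(nm) switch(nm,
    lc_rad_score = , pt_model = va(feats$pt),
    mixed_ln = cbind(lc_rad_score = predict(models$lc_rad_score, va(feats$pt)),
                     va(feats$ln)),
    mixed_lnpt = cbind(lc_rad_score = predict(models$lc_rad_score, va(feats$pt)),
                       va(feats$lnpt)),
    nstage = cbind(lc_rad_score = predict(models$lc_rad_score, va(feats$pt)),
                   n_stage = as.numeric(y_va$n_stage)))
  evaluation <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    if (is.null(m) || !m$success) next
    yv <- if (nm == "lc_rad_score") list(y_va$lc_time, y_va$lc_event)
          else list(y_va$lrc_time, y_va$lrc_event)
    evaluation[[nm]] <- evaluate_cindex(m, val_X(nm), yv[[1]], yv[[2]],
                                        n_boot = cfg$n_eval_boot,
                                        seed = eval_seed)
    logf("validation c-index %s: %.3f (%.3f-%.3f)", nm,
         evaluation[[nm]]$mean, evaluation[[nm]]$ci[1], evaluation[[nm]]$ci[2])
  }
  if (!is.null(evaluation$pt_model) && !is.null(evaluation$mixed_ln)) {
    evaluation$wilcoxon_mixed_vs_pt <-
      compare_models(evaluation$pt_model$cindex, evaluation$mixed_ln$cindex)
    logf("paired Wilcoxon mixed vs PT: p = %.4g",
         evaluation$wilcoxon_mixed_vs_pt)
  }

  ## --- stage 7: risk stratification --------------------------------------
  stratification <- list()
  for (nm in intersect(c("pt_model", "mixed_ln"), names(models))) {
    m <- models[[nm]]
    if (is.null(m) || !m$success) next
    Xtr <- if (nm == "pt_model") tr(feats$pt) else
      cbind(lc_rad_score = rs_tr, tr(feats$ln))
    r_tr <- predict(m, Xtr)
    r_va <- predict(m, val_X(nm))
    stratification[[nm]] <- tryCatch(list(
      train = stratify_risk(r_tr, y_tr$lrc_time, y_tr$lrc_event,
                            horizon = cfg$horizon),
      validation = stratify_risk(r_tr, y_tr$lrc_time, y_tr$lrc_event,
                                 risk = r_va, time = y_va$lrc_time,
                                 event = y_va$lrc_event,
                                 horizon = cfg$horizon)),
      error = function(e) { logf("stratification %s failed: %s", nm,
                                 conditionMessage(e)); NULL })
    if (!is.null(stratification[[nm]])) {
      grDevices::pdf(file.path(cfg$out_dir, sprintf("km_%s.pdf", nm)),
                     width = 8, height = 4)
      graphics::par(mfrow = c(1, 2))
      for (side in c("train", "validation"))
        if (isTRUE(stratification[[nm]][[side]]$stratified))
          plot_risk_groups(stratification[[nm]][[side]],
                           main = sprintf("%s (%s)", nm, side))
      grDevices::dev.off()
    }
  }

  ## --- manifest -----------------------------------------------------------
  manifest <- list(
    seed = cfg$seed,
    config_checksum = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
    n_patients = n, n_train = length(train_idx), n_validation = length(val_idx),
    feature_counts = lapply(feats, ncol),
    models = lapply(models, function(m)
      if (is.null(m)) "not built" else if (m$success) m$features
      else "training unsuccessful"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = feats, outcomes = outcomes,
                 split = list(train = train_idx, validation = val_idx),
                 selection = selection, models = models,
                 evaluation = evaluation, stratification = stratification,
                 manifest = manifest, out_dir = cfg$out_dir))
}
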