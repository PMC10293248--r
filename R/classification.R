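#' Model configuration for the classification pipeline
#'
#' The pipeline per training fold is: feature standardisation (zero mean,
#' unit variance), PCA over the tablet features retaining
#' `pca_variance_retained` of the training variance (the questionnaire
#' score is standardised but bypasses the PCA and enters the learner as
#' its own column — it is a different modality, not a tablet feature),
#' then a gradient-boosted decision-tree ensemble (xgboost, binary
#' logistic, library-default learning rate and depth). Scaler and PCA are
#' fitted on training folds only. Class assignment threshold is 0.5; the
#' positive class is the disease group.
#'
#' @param n_folds Stratified CV folds, default 5.
#' @param scale Standardise features, default TRUE.
#' @param pca Apply PCA, default TRUE.
#' @param pca_variance_retained Training variance retained, default 0.95.
#' @param nrounds Boosting rounds, default 100.
#' @param seed Integer seed controlling fold assignment and the learner.
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_folds = 5, scale = TRUE, pca = TRUE,
                         pca_variance_retained = 0.95, nrounds = 100,
                         seed = 1) {
  stopifnot(n_folds >= 2, pca_variance_retained > 0,
            pca_variance_retained <= 1, nrounds >= 1)
  structure(list(n_folds = n_folds, scale = scale, pca = pca,
                 pca_variance_retained = pca_variance_retained,
                 nrounds = nrounds, seed = as.integer(seed)),
            class = "model_config")
}

#' Assemble the labelled dataset of one task and feature set
#'
#' Restricts a cohort feature table to the task's groups and to one of the
#' three ablation feature sets: `questionnaire_only` (QYes alone),
#' `tablet_only` (F1c–F13) or `integrated` (all 14).
#'
#' @param features Feature table from [extract_features()].
#' @param task A [task_spec()] or its name.
#' @param feature_set `"questionnaire_only"`, `"tablet_only"` or
#'   `"integrated"`.
#' @return Object of class `task_dataset`: list with `x` (numeric matrix),
#'   `y` (0/1 integer, positive class 1), `ids`, `task`, `feature_set`.
#' @export
make_task_dataset <- function(features, task, feature_set = c(
                                "integrated", "questionnaire_only",
                                "tablet_only")) {
  if (!inherits(task, "task_spec")) task <- task_spec(task)
  feature_set <- match.arg(feature_set)
  keep <- features$group %in% c(task$positive, task$negative)
  if (sum(features$group %in% task$positive) == 0L ||
      sum(features$group %in% task$negative) == 0L) {
    stop(sprintf("validation error: empty group for %s", task$name))
  }
  cols <- switch(feature_set,
    questionnaire_only = "QYes",
    tablet_only = setdiff(feature_names(), "QYes"),
    integrated = feature_names()
  )
  sub <- features[keep, , drop = FALSE]
  x <- as.matrix(sub[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  structure(
    list(x = x, y = task_labels(sub, task), ids = sub$participant_id,
         task = task, feature_set = feature_set),
    class = "task_dataset"
  )
}

# stratified fold assignment: returns list of test-index vectors
stratified_folds <- function(y, k) {
  caret::createFolds(factor(y), k = k, list = TRUE, returnTrain = FALSE)
}

# fit standardisation on training rows; zero-variance columns pass through
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(scaler, x) {
  scale(x, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

fit_xgb <- function(x, y, config) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", nthread = 1,
                  seed = config$seed),
    data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1),
    nrounds = config$nrounds, verbose = 0
  )
}

# binary classification metrics for the positive class
binary_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  c(accuracy = mean(truth == pred),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn))
}

#' Stratified cross-validation of the scaler–PCA–boosted-tree pipeline
#'
#' For each of `n_folds` stratified folds the scaler and PCA are fitted on
#' the training portion only, the boosted-tree ensemble is trained on the
#' retained components, and the held-out fold is predicted. A companion
#' model trained on the standardised but unreduced features of the same
#' training fold is kept for per-feature SHAP attribution (principal
#' components are not attributable to named features).
#'
#' @param ds A [make_task_dataset()] dataset.
#' @param config A [model_config()].
#' @param keep_models Retain per-fold model objects (needed for
#'   [shap_importance()]); default TRUE.
#' @param leaky_preprocessing Fit scaler and PCA on all rows instead of the
#'   training fold only. Exists solely so tests can demonstrate that the
#'   default is leak-free; never enable it for results.
#' @return Object of class `cv_result`: per-fold metrics, their means,
#'   pooled out-of-fold predictions, and (optionally) fold models.
#' @export
run_cv <- function(ds, config = model_config(), keep_models = TRUE,
                   leaky_preprocessing = FALSE) {
  stopifnot(inherits(ds, "task_dataset"))
  if (min(table(ds$y)) < config$n_folds) {
    stop(sprintf(
      "validation error: smallest class has %d members; use fewer than %d folds",
      min(table(ds$y)), config$n_folds))
  }
  set.seed(config$seed)
  folds <- stratified_folds(ds$y, config$n_folds)
  fold_metrics <- vector("list", length(folds))
  fold_models <- vector("list", length(folds))
  oof <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    test_idx <- folds[[i]]
    train_idx <- setdiff(seq_along(ds$y), test_idx)
    fit_rows <- if (leaky_preprocessing) seq_along(ds$y) else train_idx
    scaler <- fit_scaler(ds$x[fit_rows, , drop = FALSE])
    xtr_s <- apply_scaler(scaler, ds$x[train_idx, , drop = FALSE])
    xte_s <- apply_scaler(scaler, ds$x[test_idx, , drop = FALSE])
    pca_cols <- which(colnames(ds$x) != "QYes")
    if (config$pca && length(pca_cols) > 1L) {
      pca_input <- if (leaky_preprocessing) {
        apply_scaler(scaler, ds$x)[, pca_cols, drop = FALSE]
      } else {
        xtr_s[, pca_cols, drop = FALSE]
      }
      pca <- prcomp(pca_input, center = FALSE, scale. = FALSE)
      cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
      ncomp <- max(1L, which(cumvar >= config$pca_variance_retained)[1L])
      rot <- pca$rotation[, seq_len(ncomp), drop = FALSE]
      project <- function(xs) {
        out <- cbind(xs[, -pca_cols, drop = FALSE],
                     xs[, pca_cols, drop = FALSE] %*% rot)
        colnames(out) <- c(colnames(ds$x)[-pca_cols],
                           paste0("PC", seq_len(ncomp)))
        out
      }
      xtr <- project(xtr_s)
      xte <- project(xte_s)
    } else {
      rot <- NULL
      xtr <- xtr_s
      xte <- xte_s
      colnames(xtr) <- colnames(xte) <- colnames(ds$x)
    }
    booster <- fit_xgb(xtr, ds$y[train_idx], config)
    prob <- predict(booster, xgboost::xgb.DMatrix(xte, nthread = 1))
    pred <- as.integer(prob > 0.5)
    fold_metrics[[i]] <- binary_metrics(ds$y[test_idx], pred)
    oof[[i]] <- tibble::tibble(
      participant_id = ds$ids[test_idx], fold = i,
      truth = ds$y[test_idx], prob = prob, pred = pred)
    if (keep_models) {
      shap_booster <- fit_xgb(
        `colnames<-`(xtr_s, colnames(ds$x)), ds$y[train_idx], config)
      fold_models[[i]] <- list(scaler = scaler, rotation = rot,
                               booster = booster,
                               shap_booster = shap_booster,
                               test_idx = test_idx, train_idx = train_idx)
    }
  }
  metrics <- do.call(rbind, fold_metrics)
  structure(
    list(task = ds$task$name, feature_set = ds$feature_set,
         fold_metrics = tibble::as_tibble(cbind(fold = seq_along(folds),
                                                as.data.frame(metrics))),
         means = colMeans(metrics, na.rm = TRUE),
         oof = do.call(rbind, oof),
         fold_models = if (keep_models) fold_models else NULL,
         folds = folds, config = config, dataset = ds),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s: accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f\n",
              x$task, x$feature_set, x$means[["accuracy"]],
              x$means[["precision"]], x$means[["recall"]], x$means[["f1"]]))
  invisible(x)
}

#' Majority-class (dummy) baseline accuracy
#'
#' Mean test accuracy of the always-majority predictor under the same
#' stratified fivefold scheme as the real models: per fold the majority
#' class of the training portion is predicted for every test sample. Up to
#' fold-size rounding this equals the majority class proportion.
#'
#' @param labels 0/1 (or factor) class labels.
#' @param n_folds Folds, default 5.
#' @param seed Seed for fold assignment.
#' @return Mean cross-validated accuracy.
#' @export
majority_baseline <- function(labels, n_folds = 5, seed = 1) {
  if (length(unique(labels)) < 2L) {
    warning("single-class input; majority baseline is trivially 1")
    return(1)
  }
  set.seed(seed)
  folds <- stratified_folds(labels, n_folds)
  accs <- vapply(folds, function(test_idx) {
    train <- labels[-test_idx]
    maj <- names(sort(table(train), decreasing = TRUE))[1L]
    mean(as.character(labels[test_idx]) == maj)
  }, numeric(1))
  mean(accs)
}

#' Ablation suite: four estimators, three tasks
#'
#' Reproduces the ablation layout of the study: for each task the
#' majority-class dummy, the questionnaire-only model, the tablet-only
#' model and the integrated model are cross-validated and their mean
#' accuracies collected; precision, recall and F1 are reported for the
#' integrated model.
#'
#' @param features Cohort feature table.
#' @param config A [model_config()].
#' @param tasks Task names, default all three.
#' @param keep_models Keep per-fold models of the integrated runs (for
#'   SHAP); default FALSE.
#' @return List with `table` (tibble: task, estimator, accuracy, precision,
#'   recall, f1) and `cv` (nested list of `cv_result` objects).
#' @export
ablation_suite <- function(features, config = model_config(),
                           tasks = c("Task1", "Task2", "Task3"),
                           keep_models = FALSE) {
  rows <- list()
  cvs <- list()
  for (tk in tasks) {
    ds_int <- make_task_dataset(features, tk, "integrated")
    rows[[paste0(tk, "_dummy")]] <- tibble::tibble(
      task = tk, estimator = "dummy",
      accuracy = majority_baseline(ds_int$y, config$n_folds, config$seed),
      precision = NA_real_, recall = NA_real_, f1 = NA_real_)
    for (fs in c("questionnaire_only", "tablet_only", "integrated")) {
      cv <- run_cv(make_task_dataset(features, tk, fs), config,
                   keep_models = keep_models && fs == "integrated")
      cvs[[tk]][[fs]] <- cv
      rows[[paste0(tk, "_", fs)]] <- tibble::tibble(
        task = tk, estimator = fs, accuracy = cv$means[["accuracy"]],
        precision = if (fs == "integrated") cv$means[["precision"]] else NA_real_,
        recall = if (fs == "integrated") cv$means[["recall"]] else NA_real_,
        f1 = if (fs == "integrated") cv$means[["f1"]] else NA_real_)
    }
  }
  list(table = do.call(rbind, unname(rows)), cv = cvs)
}

#' Per-fold mean SHAP feature importances
#'
#' For each CV fold, double-precision TreeSHAP contributions
#' ([treeshap_values()]) of the fold's companion model (trained on
#' standardised, unreduced features) are computed on the fold's held-out
#' samples and averaged per feature, giving the five per-fold mean SHAP
#' values whose distribution summarises feature importance.
#'
#' @param cv A [run_cv()] result with `keep_models = TRUE`.
#' @return Object of class `importance_report`: tibble with columns
#'   feature, fold, mean_shap, mean_abs_shap.
#' @export
shap_importance <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  if (is.null(cv$fold_models)) {
    stop("validation error: run_cv must keep models for SHAP analysis")
  }
  rows <- lapply(seq_along(cv$fold_models), function(i) {
    fm <- cv$fold_models[[i]]
    xte <- apply_scaler(fm$scaler,
                        cv$dataset$x[fm$test_idx, , drop = FALSE])
    colnames(xte) <- colnames(cv$dataset$x)
    sv <- treeshap_values(fm$shap_booster, xte)
    phi <- sv$phi[, colnames(cv$dataset$x), drop = FALSE]
    tibble::tibble(feature = colnames(phi), fold = i,
                   mean_shap = colMeans(phi),
                   mean_abs_shap = colMeans(abs(phi)))
  })
  structure(do.call(rbind, rows),
            class = c("importance_report", class(rows[[1]])))
}

#' Feature ranking by mean absolute SHAP value
#'
#' @param report An [shap_importance()] report.
#' @return Tibble: feature, importance (mean over folds of mean |SHAP|),
#'   sorted decreasing.
#' @export
shap_ranking <- function(report) {
  agg <- tapply(report$mean_abs_shap, report$feature, mean)
  tibble::tibble(feature = names(agg), importance = as.numeric(agg))[
    order(-agg), ]
}

#' Descriptive error analysis of the pooled out-of-fold predictions
#'
#' Summarises the misclassified subgroups of a task: false positives and
#' false negatives (for Task 2 the false negatives are split into their PD
#' and DD members), each with count, mean age, female count, mean QYes,
#' and mean Hoehn–Yahr where defined (PD members only). Empty subgroups
#' get count 0 and blank statistics.
#'
#' @param cv A [run_cv()] result for the task.
#' @param metadata Cohort metadata ([cohort_metadata()]) or a feature table
#'   carrying participant_id, group, age, gender, hoehn_yahr, QYes.
#' @return Tibble: error_class, n, mean_age, n_female, mean_qyes, mean_hy.
#' @export
error_analysis <- function(cv, metadata) {
  stopifnot(inherits(cv, "cv_result"))
  m <- merge(as.data.frame(cv$oof), as.data.frame(metadata),
             by = "participant_id", sort = FALSE)
  subgroup <- function(label, rows) {
    sub <- m[rows, , drop = FALSE]
    hy <- sub$hoehn_yahr[sub$group == "PD" & !is.na(sub$hoehn_yahr)]
    tibble::tibble(
      error_class = label, n = nrow(sub),
      mean_age = if (nrow(sub)) mean(sub$age) else NA_real_,
      n_female = if (nrow(sub)) sum(sub$gender == "female") else NA_integer_,
      mean_qyes = if (nrow(sub)) mean(sub$QYes) else NA_real_,
      mean_hy = if (length(hy)) mean(hy) else NA_real_)
  }
  fp <- m$truth == 0 & m$pred == 1
  fn <- m$truth == 1 & m$pred == 0
  out <- list(subgroup("FP", fp))
  if (cv$task == "Task2") {
    out <- c(out, list(subgroup("FN_PD", fn & m$group == "PD"),
                       subgroup("FN_DD", fn & m$group == "DD")))
  } else {
    out <- c(out, list(subgroup("FN", fn)))
  }
  do.call(rbind, out)
}
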