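#' Run the full assessment pipeline
#'
#' Orchestrates simulate (or load) -> feature extraction -> univariate
#' statistics -> cross-validated classification with ablations -> SHAP
#' importances -> error analysis, writing every artefact under `out_dir`:
#' `features.csv`, `stats_spearman.csv`, `stats_mwu.csv`, `ablation.csv`,
#' `ablation.json`, `shap_importance.csv`, `error_analysis.csv` and
#' `run_log.txt`. Deterministic: identical configuration gives
#' byte-identical tables.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort A [cohort_dataset()], a manifest path for [load_cohort()],
#'   or `NULL` to generate a synthetic cohort from `cohort_cfg`.
#' @param cohort_cfg A [cohort_config()] used when `cohort` is `NULL`.
#' @param config A [model_config()].
#' @param template,cfg Spiral template and spectral configuration.
#' @param write_cohort_files Also write the (possibly generated) cohort's
#'   recordings + manifest under `out_dir/cohort/`; default FALSE.
#' @return Invisibly, a list with the feature table, statistics tables,
#'   ablation report, importance reports and error analyses.
#' @export
run_pipeline <- function(out_dir, cohort = NULL,
                         cohort_cfg = cohort_config(),
                         config = model_config(),
                         template = make_reference_spiral(),
                         cfg = spectral_config(),
                         write_cohort_files = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("spiraldx %s", as.character(utils::packageVersion("spiraldx"))),
                 sprintf("model seed: %d; folds: %d; pca: %s (%.2f); nrounds: %d",
                         config$seed, config$n_folds, config$pca,
                         config$pca_variance_retained, config$nrounds),
                 "preprocessing: outward check -> distance series -> 10% edge clip (time-dependent) / top-5% magnitude removal (time-independent) -> repetition mean -> arm selection")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)))
    })
  }
  if (is.null(cohort)) {
    cohort <- stage("simulate", generate_cohort(cohort_cfg))
    log_lines <- c(log_lines, sprintf("cohort: synthetic, seed %d, n = %s",
                                      cohort_cfg$seed,
                                      paste(cohort_cfg$n_per_group,
                                            collapse = "/")))
  } else if (is.character(cohort)) {
    cohort <- stage("load", load_cohort(cohort))
    log_lines <- c(log_lines, sprintf("cohort: loaded (%d participants)",
                                      length(cohort$participants)))
  }
  if (write_cohort_files) {
    stage("write_cohort", write_cohort(cohort, file.path(out_dir, "cohort")))
  }

  features <- stage("extract", extract_features(cohort, template, cfg))
  write_feature_table(features, file.path(out_dir, "features.csv"))

  targets <- data.frame(age = features$age)
  for (tk in c("Task1", "Task2", "Task3")) {
    targets[[tk]] <- task_labels(features, tk)
  }
  sp <- stage("stats", spearman_table(features, targets))
  write.csv(sp, file.path(out_dir, "stats_spearman.csv"), row.names = FALSE)
  mwu <- do.call(rbind, lapply(c("Task1", "Task2", "Task3"), function(tk) {
    mann_whitney_tests(features, tk)
  }))
  write.csv(mwu, file.path(out_dir, "stats_mwu.csv"), row.names = FALSE)

  abl <- stage("classify", ablation_suite(features, config,
                                          keep_models = TRUE))
  write.csv(abl$table, file.path(out_dir, "ablation.csv"),
            row.names = FALSE)
  jsonlite::write_json(abl$table, file.path(out_dir, "ablation.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  meta <- cohort_metadata(cohort)
  imp <- list(); err <- list()
  for (tk in c("Task1", "Task2", "Task3")) {
    cv <- abl$cv[[tk]]$integrated
    imp[[tk]] <- stage("shap", shap_importance(cv))
    err[[tk]] <- stage("error_analysis", error_analysis(cv, meta))
  }
  imp_tbl <- do.call(rbind, lapply(names(imp), function(tk) {
    cbind(task = tk, as.data.frame(imp[[tk]]))
  }))
  write.csv(imp_tbl, file.path(out_dir, "shap_importance.csv"),
            row.names = FALSE)
  err_tbl <- do.call(rbind, lapply(names(err), function(tk) {
    cbind(task = tk, as.data.frame(err[[tk]]))
  }))
  write.csv(err_tbl, file.path(out_dir, "error_analysis.csv"),
            row.names = FALSE)

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(cohort = cohort, features = features, spearman = sp,
                 mann_whitney = mwu, ablation = abl, importance = imp,
                 errors = err))
}
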