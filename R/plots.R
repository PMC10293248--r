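#' Boxplots of a feature across task groups with significance annotation
#'
#' Log-scale boxplots (via [log_transform_features()]) of one motor
#' feature per task comparison, annotated with the Bonferroni-corrected
#' Mann–Whitney significance label. QYes is plotted untransformed.
#'
#' @param features Cohort feature table.
#' @param feature Feature column name.
#' @param c Bonferroni test count, default 14.
#' @return A ggplot object.
#' @export
plot_feature_boxplots <- function(features, feature, c = 14) {
  tasks <- c("Task1", "Task2", "Task3")
  dat <- do.call(rbind, lapply(tasks, function(tk) {
    ts <- task_spec(tk)
    keep <- features$group %in% c(ts$positive, ts$negative)
    data.frame(task = tk,
               side = ifelse(features$group[keep] %in% ts$positive,
                             paste(ts$positive, collapse = "+"),
                             paste(ts$negative, collapse = "+")),
               value = features[[feature]][keep])
  }))
  ann <- do.call(rbind, lapply(tasks, function(tk) {
    res <- mann_whitney_tests(features, tk, feature_cols = feature, c = c)
    data.frame(task = tk, label = res$annotation)
  }))
  logscale <- feature != "QYes"
  if (logscale) dat$value <- log_transform_features(dat$value)
  ggplot2::ggplot(dat, ggplot2::aes(x = side, y = value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~task, scales = "free_x") +
    ggplot2::geom_text(data = ann, size = 5,
                       ggplot2::aes(x = 1.5, y = Inf, label = label),
                       vjust = 1.5, inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, title = feature,
                  y = if (logscale) "log(value)" else "value") +
    ggplot2::theme_bw()
}

#' Boxplots of per-fold mean SHAP values per feature
#'
#' Each box is the distribution of one feature's per-fold mean SHAP value
#' over the cross-validation folds, ordered by mean absolute importance.
#'
#' @param report An [shap_importance()] report.
#' @return A ggplot object.
#' @export
plot_shap_importance <- function(report) {
  ord <- shap_ranking(report)$feature
  dat <- as.data.frame(report)
  dat$feature <- factor(dat$feature, levels = rev(ord))
  ggplot2::ggplot(dat, ggplot2::aes(x = mean_shap,
                                    y = feature)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = "mean SHAP value per fold (model output scale)",
                  y = NULL) +
    ggplot2::theme_bw()
}
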