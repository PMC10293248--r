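#!/usr/bin/env Rscript
# Univariate statistics on the extracted features: Spearman correlation of
# each feature with age and the three task labels, and Mann-Whitney U
# group comparisons per task with Bonferroni correction (c = 14).
# Writes results/stats_spearman.csv, results/stats_mwu.csv and log-scale
# boxplots for the strongest features under results/figures/.

suppressMessages(library(spiraldx))

features <- read.csv("results/features.csv")

targets <- data.frame(age = features$age)
for (tk in c("Task1", "Task2", "Task3")) {
  targets[[tk]] <- task_labels(features, tk)
}
sp <- spearman_table(features, targets)
write.csv(sp, "results/stats_spearman.csv", row.names = FALSE)
sig <- sp[sp$significant & sp$target != "age", ]
message(sprintf("%d significant feature-task correlations (threshold %.4f):",
                nrow(sig), bonferroni_threshold()))
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %-28s %s rho=%+.2f %s", sig$feature[i], sig$target[i],
                  sig$rho[i], sig$annotation[i]))
}

mwu <- do.call(rbind, lapply(c("Task1", "Task2", "Task3"), function(tk) {
  mann_whitney_tests(features, tk)
}))
write.csv(mwu, "results/stats_mwu.csv", row.names = FALSE)
message(sprintf("Mann-Whitney: %d of %d feature-task tests significant",
                sum(mwu$significant), nrow(mwu)))

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
# plot the three features most correlated with any task, plus QYes
ranked <- sig[order(-abs(sig$rho)), ]
top <- unique(c("QYes", head(ranked$feature, 3)))
for (f in top) {
  ggplot2::ggsave(file.path("results/figures", paste0("boxplot_", f, ".pdf")),
                  plot_feature_boxplots(features, f), width = 7, height = 3.5)
}
message("statistics tables and boxplots written under results/")
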