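#!/usr/bin/env Rscript
# Descriptive statistics of the misclassified subgroups: for each task the
# pooled out-of-fold predictions of the integrated classifier are split
# into false positives and false negatives (Task 2 FNs by PD/DD), each
# summarised by count, mean age, female count, mean QYes and mean
# Hoehn-Yahr stage where defined. Writes results/error_analysis.csv.
#
# Usage: Rscript analysis/06_error_analysis.R [seed]  (same seed as 04)

suppressMessages(library(spiraldx))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

features <- read.csv("results/features.csv")
meta <- features[, c("participant_id", "group", "age", "gender",
                     "hoehn_yahr", "QYes")]

rows <- list()
for (tk in c("Task1", "Task2", "Task3")) {
  cv <- run_cv(make_task_dataset(features, tk, "integrated"),
               model_config(seed = seed), keep_models = FALSE)
  ea <- error_analysis(cv, meta)
  rows[[tk]] <- cbind(task = tk, as.data.frame(ea))
  for (i in seq_len(nrow(ea))) {
    message(sprintf("%s %-6s n=%2d mean age %s, females %s, mean QYes %s",
                    tk, ea$error_class[i], ea$n[i],
                    ifelse(is.na(ea$mean_age[i]), "-",
                           sprintf("%.1f", ea$mean_age[i])),
                    ifelse(is.na(ea$n_female[i]), "-", ea$n_female[i]),
                    ifelse(is.na(ea$mean_qyes[i]), "-",
                           sprintf("%.1f", ea$mean_qyes[i]))))
  }
}
write.csv(do.call(rbind, rows), "results/error_analysis.csv",
          row.names = FALSE)
message("error analysis written to results/error_analysis.csv")
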