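#!/usr/bin/env Rscript
# Generate the default synthetic cohort (27 CG / 24 PD / 26 DD, two-handed
# spiral recordings at 240 Hz plus 30-item questionnaires) and write it as
# a portable recording-CSV + JSON-manifest bundle under results/cohort/.
#
# Usage: Rscript analysis/01_simulate_cohort.R [seed]

suppressMessages(library(spiraldx))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cc <- cohort_config(seed = seed)
cohort <- generate_cohort(cc)
print(cohort)

manifest <- write_cohort(cohort, "results/cohort")
meta <- cohort_metadata(cohort)
message(sprintf("median age CG/PD/DD: %s",
                paste(tapply(meta$age, meta$group, median)[c("CG","PD","DD")], collapse = "/")))
message(sprintf("mean QYes CG/PD/DD: %s",
                paste(round(tapply(meta$QYes, meta$group, mean)[c("CG","PD","DD")], 1),
                      collapse = "/")))
message("cohort written to ", manifest)
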