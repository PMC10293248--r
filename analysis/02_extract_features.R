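#!/usr/bin/env Rscript
# Load the cohort written by 01_simulate_cohort.R and compute the feature
# table: QYes plus the 13 motor features (distance precision, tremor-band
# spectral laterality, direction changes, force and kinematics), taken from
# the stronger-affected arm after the outlier rules and repetition
# averaging. Writes results/features.csv.

suppressMessages(library(spiraldx))

cohort <- load_cohort("results/cohort")
features <- extract_features(cohort)
write_feature_table(features, "results/features.csv")

message(sprintf("extracted %d x %d feature table", nrow(features),
                length(feature_names())))
for (f in c("F2_MaxDistance", "F5_ChangeOfRadiusDirection",
            "F11_TimeOfDrawing")) {
  message(sprintf("%s group means CG/PD/DD: %s", f,
                  paste(signif(tapply(features[[f]], features$group, mean)[c("CG","PD","DD")], 3),
                        collapse = "/")))
}
message("feature table written to results/features.csv")
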