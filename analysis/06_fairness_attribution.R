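#!/usr/bin/env Rscript
# Step 6 — interpretability and fairness.
# Reports the probability-severity profile (mean predicted ADRD probability
# per cognitive band), the globally most influential linguistic features
# from the path-decomposition attributions, and subgroup performance with
# demographic-parity and equalized-odds gaps.

library(speechscreen)

profile <- read.csv("results/study/probability_severity_profile.csv")
ranking <- read.csv("results/study/attribution_ranking.csv")
subgroups <- read.csv("results/study/subgroup_performance.csv")
metrics <- jsonlite::read_json("results/study/metrics.json",
                               simplifyVector = TRUE)

cat("mean predicted ADRD probability by cognitive group (test set):\n")
print(profile, row.names = FALSE)

cat("\ntop 12 features by mean |contribution| to the predicted probability:\n")
print(head(ranking, 12), row.names = FALSE)

cat("\nsubgroup performance (threshold 0.5):\n")
print(subgroups, row.names = FALSE)

cat(sprintf("\ndemographic parity gap (sex): %.3f\n", metrics$parity$sex_gap))
cat(sprintf("equalized-odds gaps (sex): sensitivity %.3f, specificity %.3f\n",
            metrics$parity$odds$sensitivity_gap,
            metrics$parity$odds$specificity_gap))
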