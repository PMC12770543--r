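#!/usr/bin/env Rscript
# Step 3 — fit and evaluate the screening models.
# Runs the full study on the simulated cohort: 10-fold stratified CV of the
# ADRD detector (RF, 50 trees, depth 16) and MMSE regressor (RF, min 2
# samples/leaf) on the train split, 10-repeat bootstrap evaluation on the
# fixed test split, calibration of out-of-fold probabilities, traffic-light
# threshold search, attributions and fairness tables. Writes the complete
# report bundle under results/study/.

library(speechscreen)

seed <- 11L
cohort <- read_cohort("results/cohort/transcripts", "results/cohort/metadata.csv")
study <- run_screening_study(cohort, seed = seed)
write_study_reports(study, "results/study")

print(study)
cv <- study$detect$cv$summary
cat("\ndetector 10-fold CV, mean (SD) %:\n")
print(cv, row.names = FALSE)
cat("\ndetector test set, bootstrap mean [95% interval] %:\n")
print(study$detect$bootstrap$summary, row.names = FALSE)
cat("\nregressor test set, bootstrap mean [95% interval] (MMSE points):\n")
print(study$severity$bootstrap$summary, row.names = FALSE)
cat("\ncalibration of out-of-fold probabilities (bin score vs event rate):\n")
print(study$detect$calibration, row.names = FALSE)
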