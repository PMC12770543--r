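#!/usr/bin/env Rscript
# Step 5 — traffic-light triage.
# Summarises the threshold search from step 3 (grid over validation
# out-of-fold scores, ranked by retained Youden's J, then ROC-AUC, then
# coverage, ties to smaller thresholds), the resulting Green/Amber/Red
# zone distribution across severity bands on the test set, and the
# selective-classification gain from abstaining on Amber.

library(speechscreen)

zones <- read.csv("results/study/risk_zones.csv")
trace <- read.csv("results/study/threshold_search_trace.csv")
metrics <- jsonlite::read_json("results/study/metrics.json",
                               simplifyVector = TRUE)

cat(sprintf("selected thresholds: Green [0, %.2f], Amber (%.2f, %.2f], Red (%.2f, 1]\n",
            trace$t_low[1], trace$t_low[1], trace$t_high[1], trace$t_high[1]))
cat(sprintf("feasible grid pairs examined: %d\n", nrow(trace)))

dist_tab <- table(zone = zones$zone, group = factor(
  zones$mmse_group, levels = c("CN", "MCI", "moderate", "severe")))
write.csv(as.data.frame(dist_tab),
          "results/study/zone_distribution_by_group.csv", row.names = FALSE)
cat("\nzone distribution by cognitive group (test set):\n")
print(dist_tab)

sel <- metrics$selective
full <- metrics$detect
cat(sprintf("\nfull coverage:   sens %.1f%%  spec %.1f%%  AUC %.1f%%  acc %.1f%%\n",
            full$sensitivity, full$specificity, full$roc_auc, full$accuracy))
cat(sprintf("Amber excluded:  sens %.1f%%  spec %.1f%%  AUC %.1f%%  acc %.1f%%  (coverage %.0f%%)\n",
            sel$sensitivity, sel$specificity, sel$roc_auc, sel$accuracy,
            100 * sel$coverage))
cat(sprintf("specificity gain from triage: %+.1f points; retained Youden's J %.2f\n",
            sel$specificity - full$specificity, sel$youden_j))
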