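#!/usr/bin/env Rscript
# Step 4 — severity-prediction error by cognitive group.
# Reads the per-participant MMSE predictions from step 3 and tabulates the
# mean absolute error within each severity band, the usual way to show
# where a severity model is reliable (errors grow toward the severe end,
# which is sparsely represented).

library(speechscreen)

pred <- read.csv("results/study/severity_predictions.csv")
pred$abs_err <- abs(pred$mmse - pred$predicted_mmse)

bands <- c("CN", "MCI", "moderate", "severe")
tab <- do.call(rbind, lapply(bands[bands %in% pred$mmse_group], function(g) {
  e <- pred$abs_err[pred$mmse_group == g]
  data.frame(group = g, n = length(e), mae = mean(e), sd_abs_err = sd(e))
}))
write.csv(tab, "results/study/severity_mae_by_group.csv", row.names = FALSE)

overall <- regression_metrics(pred$mmse, pred$predicted_mmse)
cat(sprintf("test MAE %.2f, RMSE %.2f over %d participants\n",
            overall$mae, overall$rmse, nrow(pred)))
cat("MAE by cognitive group:\n")
print(tab, row.names = FALSE)
r <- spearman_rank(pred$mmse, pred$predicted_mmse)
cat(sprintf("Spearman(observed, predicted MMSE): r = %.2f (p = %.2g)\n",
            r$r, r$p))
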