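#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
# Draws a synthetic picture-description cohort (n = 450, balanced CN/ADRD,
# strong linguistic effects, stratified 300/150 train-test split) and writes
# it in the same on-disk layout the corpus reader expects, plus the
# generator's truth table (latent severity and target category rates).

library(speechscreen)

seed <- 11L
out_dir <- "results/cohort"

cohort <- generate_cohort(cohort_config(450L, seed = seed,
                                        train_fraction = 2 / 3))
paths <- write_cohort(cohort, out_dir)
write.csv(cohort$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)

meta <- cohort$metadata
cat(sprintf("wrote %d transcripts to %s\n", nrow(meta), paths$transcript_dir))
cat(sprintf("diagnosis: %d CN / %d ADRD; split: %d train / %d test\n",
            sum(meta$diagnosis == "CN"), sum(meta$diagnosis == "ADRD"),
            sum(meta$split == "train"), sum(meta$split == "test")))
cat(sprintf("MMSE mean (SD): %.1f (%.1f); age %.1f (%.1f); %.0f%% male\n",
            mean(meta$mmse), sd(meta$mmse), mean(meta$age), sd(meta$age),
            100 * mean(meta$sex == "male")))
print(table(mmse_group = mmse_to_group(meta$mmse), split = meta$split))
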