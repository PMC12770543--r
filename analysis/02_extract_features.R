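#!/usr/bin/env Rscript
# Step 2 — extract the interpretable 100-dimensional feature vectors.
# Reads the simulated corpus back from disk (exercising the same reader a
# real transcript corpus would use), computes the canonical feature matrix
# (5 lexical-semantic indices, words per sentence, analytic composite,
# cohort-normalised disfluency aggregate, 92 category proportions) and
# writes the feature table plus its JSON schema.

library(speechscreen)

cohort <- read_cohort("results/cohort/transcripts", "results/cohort/metadata.csv")
dict <- load_dictionary(standin_dictionary_path())
features <- extract_cohort_features(cohort$transcripts, dict)

write_feature_table(features, "results/features.csv")
write_feature_schema(dict, "results/feature_schema.json")

cat(sprintf("extracted %d x %d feature matrix -> results/features.csv\n",
            nrow(features), ncol(features) - 1L))
adrd <- cohort$metadata$diagnosis == "ADRD"
show <- c("cttr", "honore_r", "words_per_sentence", "impersonal_pronoun",
          "adverb", "family", "fulfil", "disfluency")
cat("group means (CN vs ADRD):\n")
for (f in show)
  cat(sprintf("  %-20s %8.3f  %8.3f\n", f,
              mean(features[[f]][!adrd]), mean(features[[f]][adrd])))
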