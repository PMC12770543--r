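---
title: "Methods: linguistic-feature screening of cognitive impairment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linguistic-feature screening of cognitive impairment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechscreen)
```

## The problem

Speech elicited by a structured picture-description task carries measurable
signatures of cognitive decline: people with Alzheimer's disease and related
dementias (ADRD) tend to use more pronouns (especially impersonal ones:
"that", "it", "this"), more adverbs, more disfluencies ("uh", "um", "you
know", "yeah"), shorter sentences, a narrower active vocabulary with more
repetition, fewer words expressing completion ("enough", "full", "done"),
and fewer references to family, while cognitively normal (CN) speakers
produce more analytic, article- and preposition-heavy descriptions.
`speechscreen` turns participant-level transcripts of such descriptions into
an interpretable feature vector, trains Random Forest models for two tasks —
binary ADRD detection and Mini-Mental State Examination (MMSE, 0–30)
severity regression — and post-processes the predicted probabilities into a
clinically oriented Green/Amber/Red triage scheme with fairness and
attribution reporting.

Clinical speech corpora in this area are membership-gated, so the package
ships a synthetic cohort generator that reproduces the *statistical
structure* the analysis relies on. Every pipeline stage is exercised and
tested against that generator; none of the numbers the package prints on
synthetic cohorts are estimates of performance on real clinical speech.

## The feature vector

Each transcript is tokenized by a fixed, documented rule (lowercase;
a token is a maximal run of letters/digits with optional internal
apostrophes; sentences split on `.`, `!`, `?` before whitespace or end; a
transcript without terminal punctuation is one sentence). From the token
stream we compute exactly 100 features, in a canonical order:

1. **Five lexical-semantic indices.** Corrected type-token ratio
   (Carroll's CTTR, $V/\sqrt{2N}$), Brunet's index
   ($W = N^{V^{-0.165}}$, lower = richer vocabulary), Honoré's statistic
   ($R = 100\ln N / (1 - V_1/V)$, with $V_1$ the hapax count),
   propositional idea density, and the count of consecutive duplicate
   words. $N$, $V$, $V_1$ are token, type and hapax counts.
2. **Words per sentence** ($N$ / number of sentences).
3. **An analytic-thinking composite**, the categorical-dynamic form
   $30 + \text{article} + \text{preposition} - \text{personal pronoun} -
   \text{impersonal pronoun} - \text{auxiliary verb} - \text{conjunction} -
   \text{adverb} - \text{negation}$ with inputs as percentages of tokens,
   clamped to $[0, 100]$.
4. **A disfluency aggregate**: the sum of the nonfluency, filler and assent
   category proportions, z-scored across the cohort (zero variance maps
   to 0). This is the only cohort-dependent feature, which is why
   `extract_features()` returns the raw sum and `extract_cohort_features()`
   applies the normalisation.
5. **92 dictionary category proportions**, one per category of the bundled
   dictionary, each the fraction of tokens matching the category's
   patterns.

### Numerical choices and degenerate inputs

* Empty transcripts are an error (named by participant) for the indices that
  are undefined at $N = 0$; category proportions on an empty stream are
  defined as all-zero with a warning.
* Honoré's statistic diverges when every type is a hapax ($V_1 = V$); the
  denominator is floored at $1/(2V)$, capping $R$ at $200\,V \ln N$.
* The literature names "corrected" TTR without fixing a formula; we use
  Carroll's variant. Brunet's constant is the classical 0.165.
* Idea density is operationalized as the proportion of tokens tagged VERB,
  ADJ, ADV, ADP or CONJ. No automated proposition counter is assumed: the
  package ships a deterministic rule-based tagger (closed-class lexicon plus
  suffix heuristics, NOUN as the open-class default) behind the `pos_tag()`
  interface. Auxiliaries are tagged VERB so "is" in "the boy is falling"
  carries a proposition. The tagger is crude by design — idea density only
  needs a stable proposition/non-proposition split, and a deterministic rule
  keeps every downstream number reproducible.

### The stand-in dictionary

Proprietary psycholinguistic dictionaries cannot be redistributed, and their
word lists are not the reproducible content of this pipeline — the counting
mechanics are. The bundled dictionary (`standin_dictionary_path()`) is an
original, openly authored 92-category list with the same mechanics: literal
tokens, `*` prefix wildcards ("know*" matches "knows", "knowing"), and
underscore bigrams ("you_know" matches the adjacent pair "you know",
counted against $N$). It includes the categories the analysis depends on
(personal/impersonal pronouns, articles, prepositions, auxiliary verbs,
conjunctions, negations, adverbs, family, fulfil, nonfluency, filler,
assent) plus enough further categories to fill the conventional
100-dimension layout. A token may match several categories.

## The synthetic cohort generator

The generator is the package's substitute for access-restricted clinical
corpora, and its defaults define the study conditions used by the tests:

* **Latent severity** $s \in [0, 1]$ drives everything. CN participants
  draw $s \sim 0.35\,\mathrm{Beta}(1.5, 2.5)$, ADRD participants
  $s \sim 0.35 + 0.65\,\mathrm{Beta}(1.1, 1.5)$; the diagnosis boundary at
  $s = 0.35$ makes the ADRD class span mild-to-severe disease, as an
  all-cause clinical dementia label does. The ADRD shape parameters were
  chosen so the severe MMSE band holds roughly 4–6% of a cohort — matching
  the sparse severe representation typical of these corpora — rather than
  being a vanishing tail.
* **MMSE** $= \mathrm{clamp}(\mathrm{round}(29 - 22s + \varepsilon), 0, 30)$
  with $\varepsilon \sim N(0, 1.5^2)$, mapping $s = 0$ to 29 and $s = 1$
  to 7. The resulting cohort MMSE mean (≈ 20–21, SD ≈ 6–7) sits near the
  low-20s mean with SD ≈ 7 that screening cohorts of this design report.
* **Demographics**: age $\sim N(68, 6.8^2)$ years, 34% male, drawn
  independently of diagnosis — the generator is sex-fair by construction,
  which is what makes the parity checks falsifiable tests of the *pipeline*
  rather than of the data.
* **Transcripts**: tokens are drawn sentence by sentence. Each position
  either fires one of 13 controlled categories — with pronoun, impersonal
  pronoun, adverb, nonfluency, filler and assent rates increasing in $s$,
  and article, preposition, family and fulfil rates decreasing — or draws a
  content word from a Zipf-weighted pool whose active size shrinks by up to
  70% as $s \to 1$ (lowering CTTR and Honoré). Mean sentence length falls
  from 11 to 6 tokens and the adjacent-duplicate probability rises from
  0.01 to 0.11 across the severity range. The content pool is built from
  the dictionary's concrete categories and excludes anything matching a
  controlled category, so the manipulated rates stay exact.
* **Effect size**: `"strong"` applies the shifts above, `"weak"` halves
  them, `"none"` removes them entirely — under the null, transcripts are
  independent of severity and diagnosis, which is what the chance-level
  calibration tests exploit.
* **Determinism**: each participant has an RNG stream derived from
  `(seed, index)`, so a fixed seed yields byte-identical cohorts and
  adding participants never reshuffles existing ones. The 70:30
  train/test split is stratified by diagnosis (`train_fraction` is
  configurable; the reference evaluation uses 2/3 at $n = 450$ for a
  300/150 split).

The magnitudes of the linguistic shifts are calibration choices of the
generator, not empirical claims: no quantitative effect sizes for these
differences are established, only directions. Consequently the generator
supports *property* tests — directions recovered, null at chance, severity
ordering — not numerical reproduction of clinical results. Passing tests
show the pipeline is correct and well-behaved, not that it would achieve
any particular accuracy on real speech, which also lacks the closed
lexicon, clean sentence boundaries and exact category control of the
synthetic text.

## Models and evaluation protocol

Both models are Random Forests (via `ranger`, single-threaded and seeded
for exact reproducibility): the detector a probability forest of 50 trees
with maximum depth 16, the severity regressor a forest with a minimum of
two samples per leaf. These are the tuned values for this problem class;
the constructor exposes them as defaults rather than re-running the search.
Other forest internals follow the ranger defaults and are recorded in the
run manifest.

* **Cross-validation**: 10-fold, stratified by label for detection. Every
  training sample is scored exactly once out-of-fold; fold metrics are
  reported as mean (SD). The out-of-fold scores double as the validation
  scores for calibration checks and threshold search.
* **Test evaluation**: 10 bootstrap repeats; each repeat resamples the
  training set with replacement, refits, and evaluates on the *fixed* test
  set. We summarise as mean ± 1.96·SD across repeats: with only 10
  repeats a percentile interval is too coarse and the
  $\mathrm{SD}/\sqrt{B}$ standard error understates variability; the
  SD-based band matches the "performance variability" reading. Single-class
  bootstrap draws are rejected and redrawn (bounded retries).
* **Metrics**: sensitivity, specificity, accuracy and ROC-AUC in percent
  for detection (AUC via the rank identity, equal to pairwise concordance
  with ties counting ½); MAE and RMSE in MMSE points for severity.
  Single-class inputs flag the undefined metrics instead of propagating
  NaN. The class threshold for sensitivity/specificity/accuracy is 0.5
  unless triage thresholds are in play; the operating point is otherwise
  unspecified in this problem class.
* **Severity bands**: CN (26, 30], MCI (20, 26], moderate [10, 20],
  severe [0, 10), with the printed boundary conventions (26 is MCI; 20 and
  10 are moderate; 9 is severe). The binary screening cutoff labels
  MMSE ≤ 26 impaired.

## Traffic-light triage

Predicted probabilities are stratified into Green `[0, t_low]`, Amber
`(t_low, t_high]`, Red `(t_high, 1]`. Following selective classification,
Amber (the model's uncertainty region) is excluded; retained Green cases
count as negative predictions and Red as positive. We read Green as low
risk and Red as high risk throughout; the opposite assignment (Green =
predicted positive) appears once in the source literature's methods prose
but contradicts its own figures and risk-level definitions, and we treat
it as a typo.

Thresholds are chosen by exhaustive grid search over all `t_low <= t_high`
pairs on the validation (out-of-fold) scores, default resolution 0.05 —
finer than the 0.10 sometimes quoted, because reference operating points
like 0.45/0.65 do not lie on a 0.10 grid. Pairs with coverage below 0.5 or
undefined retained metrics are infeasible; the rest are ranked
lexicographically by retained Youden's J ($J = \text{sens} + \text{spec}
- 1$), then retained ROC-AUC, then coverage, with exact ties resolved to
the smaller threshold pair (a guard against overfitting small validation
sets). The lexicographic rule is our resolution of a multi-objective
description that names J, AUC and coverage without weights; the
`min_coverage = 0.5` floor operationalizes "optimising coverage", which is
otherwise unquantified. The full search trace is returned and written out.

## Attribution, calibration, fairness

* **Tree attributions** use exact path decomposition (the Saabas method):
  each node of each tree is assigned its in-bag mean outcome — computed by
  routing the in-bag training samples down the stored split structure,
  which reproduces ranger's leaf values exactly — and the value change
  across every split on a sample's path is credited to the split feature.
  The method is *locally accurate by construction*: base value plus the sum
  of a sample's contributions equals the forest's prediction (verified to
  1e-6 in the tests, observed at machine precision). On depth-1 trees it
  coincides with the exact Shapley value; on deeper trees it is a
  path-dependent approximation that favours features used near the root of
  the specific path taken. A permutation mode (mean absolute prediction
  change under column shuffles) provides a model-agnostic global ranking.
* **Calibration** is assessed on the out-of-fold scores with equal-width
  probability bins (mean score vs event rate per non-empty bin), plus the
  probability-severity profile: mean predicted probability per MMSE band,
  which should rise monotonically CN → severe, and the Spearman
  correlation between score and MMSE, which should be negative. Spearman is
  computed from mid-ranks with the two-sided t approximation.
* **Fairness**: demographic parity gap (max pairwise difference in
  positive-prediction rates over groups), equalized-odds style
  sensitivity/specificity gaps, and full per-subgroup metric tables for sex
  and a median-split age band (no standard age bins exist for this task, so
  the median split keeps both groups powered). Small groups are flagged,
  not dropped.

## Problem sizes used by the tests and acceptance runs

The reference evaluation run generates $n = 450$ (300 train / 150 test,
strong effects, seed fixed); direction-recovery checks use $n = 300$;
the null-calibration check averages test ROC-AUC over 10 cohorts of
$n = 500$ with `effect_size = "none"`; the fairness check uses $n = 400$.
These sizes give the Monte-Carlo properties comfortable margins (e.g. the
null band [0.40, 0.60] and the 0.15 parity-gap bound) while keeping a full
run of the suite and the acceptance script in the minutes range on a
single core.

## Known limitations

* The synthetic lexicon is closed (~250 content words) and category-pure
  by construction; real transcripts have open vocabulary, ASR errors,
  code-switching and speaker overlap, none of which are modelled.
* The rule-based tagger is not a general-purpose POS tagger; idea density
  values are only comparable within this pipeline.
* Path-decomposition attributions are not Shapley values on trees deeper
  than 1; rankings from correlated features should be read qualitatively.
* The bootstrap interval from 10 repeats characterises refit variability on
  a fixed test set, not sampling variability of the test population.
* Non-English transcripts are carried through with their language code but
  the dictionary and tagger are English-only; translation is out of scope.
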