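# independent brute-force references, kept deliberately naive
oracle_counts <- function(tokens) {
  types <- unique(tokens)
  occ <- vapply(types, function(t) sum(tokens == t), 0L)
  list(n_tokens = length(tokens), n_types = length(types),
       n_hapax = sum(occ == 1L))
}
oracle_cttr <- function(tokens) {
  o <- oracle_counts(tokens); o$n_types / sqrt(2 * o$n_tokens)
}
oracle_brunet <- function(tokens) {
  o <- oracle_counts(tokens); o$n_tokens ^ (o$n_types ^ (-0.165))
}
oracle_honore <- function(tokens) {
  o <- oracle_counts(tokens)
  d <- 1 - o$n_hapax / o$n_types
  if (d < 1 / (2 * o$n_types)) d <- 1 / (2 * o$n_types)
  100 * log(o$n_tokens) / d
}
oracle_dups <- function(tokens) {
  k <- 0L
  for (i in seq_along(tokens)) if (i > 1L && tokens[i] == tokens[i - 1L])
    k <- k + 1L
  k
}
oracle_props <- function(tokens, dictionary) {
  match_one <- function(tok, pat) {
    if (endsWith(pat, "*")) startsWith(tok, substr(pat, 1, nchar(pat) - 1))
    else tok == pat
  }
  bigrams <- if (length(tokens) >= 2)
    paste(tokens[-length(tokens)], tokens[-1], sep = "_") else character(0)
  out <- numeric(0)
  for (cat in dictionary$category_order) {
    count <- 0L
    for (pat in dictionary$categories[[cat]]) {
      stream <- if (grepl("_", pat, fixed = TRUE)) bigrams else tokens
      for (tok in stream) if (match_one(tok, pat)) count <- count + 1L
    }
    out[cat] <- count / length(tokens)
  }
  out
}

test_that("worked examples of the lexical diversity indices are exact", {
  expect_equal(corrected_ttr(list(n_tokens = 8, n_types = 8, n_hapax = 8)), 2.0)
  expect_equal(corrected_ttr(list(n_tokens = 1, n_types = 1, n_hapax = 1)),
               1 / sqrt(2), tolerance = 1e-12)
  toks <- c("the", "boy", "is", "on", "the", "stool")
  expect_equal(corrected_ttr(lexical_counts(toks)), 5 / sqrt(12),
               tolerance = 1e-12)

  expect_equal(brunet_index(list(n_tokens = 1, n_types = 1)), 1.0)
  w50 <- brunet_index(list(n_tokens = 100, n_types = 50))
  w100 <- brunet_index(list(n_tokens = 100, n_types = 100))
  expect_equal(w50, 11.19, tolerance = 1e-3)
  expect_equal(w100, 8.62, tolerance = 1e-2)
  expect_lt(w100, w50)

  expect_equal(honore_index(lexical_counts(c("a", "b", "c", "a"))),
               100 * log(4) / (1 - 2 / 3), tolerance = 1e-12)
  expect_equal(honore_index(lexical_counts(rep("a", 5))), 100 * log(5),
               tolerance = 1e-12)
  # all-hapax degenerate case: denominator floored at 1/(2V)
  expect_equal(honore_index(lexical_counts(c("a", "b", "c"))),
               100 * log(3) * 2 * 3, tolerance = 1e-12)
  expect_error(corrected_ttr(lexical_counts(character(0))), "empty")
})

test_that("lexical indices match brute-force references on random streams", {
  set.seed(42)
  for (i in 1:100) {
    toks <- random_token_stream(sample(1:120, 1), vocab_size = sample(3:60, 1))
    cnt <- lexical_counts(toks)
    expect_true(cnt$n_hapax <= cnt$n_types && cnt$n_types <= cnt$n_tokens)
    expect_equal(corrected_ttr(cnt), oracle_cttr(toks), tolerance = 1e-9)
    expect_equal(brunet_index(cnt), oracle_brunet(toks), tolerance = 1e-9)
    expect_equal(honore_index(cnt), oracle_honore(toks), tolerance = 1e-9)
    expect_equal(consecutive_duplicates(toks), oracle_dups(toks))
  }
})

test_that("Brunet's W strictly decreases in V at fixed N", {
  for (n in c(20, 50, 100, 400)) {
    w <- vapply(seq(2, n, by = max(1, n %/% 20)), function(v)
      brunet_index(list(n_tokens = n, n_types = v)), 0)
    expect_true(all(diff(w) < 0))
  }
})

test_that("consecutive duplicate counting handles edge cases", {
  expect_equal(consecutive_duplicates(c("the", "the", "boy")), 1L)
  expect_equal(consecutive_duplicates(c("a", "a", "a")), 2L)
  expect_equal(consecutive_duplicates(character(0)), 0L)
})

test_that("idea density counts proposition-bearing tags", {
  toks <- c("the", "boy", "is", "falling", "quickly")
  expect_identical(pos_tag(toks), c("DET", "NOUN", "VERB", "VERB", "ADV"))
  expect_equal(idea_density(toks), 3 / 5)
  expect_equal(idea_density(c("x", "y"), c("DET", "NOUN")), 0)
  expect_equal(idea_density(c("x", "y"), c("VERB", "VERB")), 1)
  expect_error(idea_density(c("a", "b"), "VERB"), "length")
})

test_that("category proportions match a naive per-token per-pattern scan", {
  d <- load_dictionary(tiny_dictionary_file(c(
    "filler: um, uh",
    "pronoun: it, he",
    "cognition: know*",
    "phrase: you_know",
    "empty_cat:")))
  p <- category_proportions(c("um", "it", "it", "runs"), d)
  expect_equal(unname(p["filler"]), 0.25)
  expect_equal(unname(p["pronoun"]), 0.5)
  expect_equal(unname(p["empty_cat"]), 0)

  p2 <- category_proportions(c("knows", "knowing", "now"), d)
  expect_equal(unname(p2["cognition"]), 2 / 3)

  p3 <- category_proportions(c("you", "know", "you", "knows"), d)
  expect_equal(unname(p3["phrase"]), 1 / 4)   # only the exact bigram

  set.seed(7)
  vocab <- c("um", "uh", "it", "he", "know", "knows", "you", "runs", "w1", "w2")
  for (i in 1:60) {
    toks <- sample(vocab, sample(2:40, 1), replace = TRUE)
    expect_equal(category_proportions(toks, d), oracle_props(toks, d),
                 tolerance = 1e-12)
  }
  expect_warning(p0 <- category_proportions(character(0), d), "empty")
  expect_true(all(p0 == 0))
})

test_that("disfluency aggregate and analytic composite follow their formulas", {
  props <- c(nonfluency = 0.02, filler = 0.01, assent = 0.03)
  expect_equal(disfluency_raw(props), 0.06)
  expect_equal(disfluency_raw(c(nonfluency = 0, filler = 0, assent = 0)), 0)
  expect_error(disfluency_raw(c(nonfluency = 0.1, filler = 0.1)), "assent")

  base <- c(article = 0, preposition = 0, personal_pronoun = 0,
            impersonal_pronoun = 0, auxiliary_verb = 0, conjunction = 0,
            adverb = 0, negation = 0)
  expect_equal(analytic_composite(base), 30)
  up <- base; up["article"] <- 0.10; up["preposition"] <- 0.10
  expect_equal(analytic_composite(up), 50)
  dn <- base; dn["adverb"] <- 0.25; dn["negation"] <- 0.15
  expect_equal(analytic_composite(dn), 0)   # clamped at 0
  expect_error(analytic_composite(base[-1]), "article")
})

test_that("words per sentence averages over transcript sentences", {
  tr <- transcript("x", "one two three. one two three four. a b c d e. w x y z.")
  expect_equal(words_per_sentence(tr), 4)
  expect_equal(words_per_sentence(transcript("y", "a b c d e f g")), 7)
  expect_error(words_per_sentence(transcript("z", "")), "empty")
})

test_that("the feature vector has the fixed shape and expected invariances", {
  d <- standin_dict()
  tr <- transcript("p1", paste(
    "the boy is on the stool reaching for the cookie jar.",
    "uh the water is overflowing in the sink.",
    "his mother is drying dishes and um she does not see it."))
  f <- extract_features(tr, d)
  expect_length(f, 100L)
  expect_identical(names(f), feature_schema(d)$name)
  expect_identical(f, extract_features(transcript("p1", tr$raw_text), d))

  cat_idx <- which(attr(f, "groups") == "category")
  expect_true(all(f[cat_idx] >= 0 & f[cat_idx] <= 1))
  expect_gte(f[["analytic_thinking"]], 0)
  expect_lte(f[["analytic_thinking"]], 100)

  # doubling the transcript: proportions invariant, CTTR shrinks
  dbl <- transcript("p1", paste(tr$raw_text, tr$raw_text))
  f2 <- extract_features(dbl, d)
  expect_equal(f2[cat_idx], f[cat_idx], tolerance = 1e-12)
  expect_lt(f2[["cttr"]], f[["cttr"]])

  expect_error(extract_features(transcript("p9", ""), d), "p9")
})

test_that("cohort extraction z-scores the disfluency aggregate", {
  st <- small_study()
  d <- st$features$disfluency
  expect_equal(mean(d), 0, tolerance = 1e-10)
  expect_equal(sd(d), 1, tolerance = 1e-10)
  # constant raw disfluency across a cohort z-scores to zero
  trs <- lapply(1:3, function(i)
    transcript(paste0("c", i), "the boy runs. the girl sits."))
  fz <- extract_cohort_features(trs, standin_dict())
  expect_true(all(fz$disfluency == 0))
})
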