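#' Synthetic cohort configuration
#'
#' The generator emulates the structure of a picture-description screening
#' cohort: two diagnosis groups (CN vs ADRD) tied to a latent severity
#' `s in [0, 1]`, MMSE inversely linked to severity, demographics matching a
#' typical training cohort (age 68 (6.8) years, 34% male), and transcript
#' effects in the directions reported for ADRD speech: more pronouns
#' (especially impersonal), adverbs and disfluencies, fewer family and
#' fulfilment words, fewer articles/prepositions, shrinking active
#' vocabulary (lower CTTR/Honore), shorter sentences and more adjacent
#' duplicate words.
#'
#' @param n_participants Cohort size (>= 2).
#' @param adrd_prevalence Fraction with ADRD (default 0.5, the roughly
#'   balanced case-control design typical of these corpora).
#' @param effect_size `"strong"`, `"weak"` (half-strength shifts) or
#'   `"none"` (all groups share one transcript distribution; the null).
#' @param age_mean,age_sd Age distribution in years.
#' @param male_fraction Probability of male sex (independent of diagnosis,
#'   so the generator is sex-fair by construction).
#' @param seed Integer master seed; fixed seed gives byte-identical cohorts.
#' @param mmse_noise_sd SD (MMSE points) of the noise on the severity-MMSE
#'   line (default 1.5).
#' @param train_fraction Fraction assigned to the train split, stratified by
#'   label (default 0.7, the usual 70:30 design; 2/3 gives a 300/150 split
#'   at n = 450).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 100L,
                          adrd_prevalence = 0.5,
                          effect_size = c("strong", "weak", "none"),
                          age_mean = 68, age_sd = 6.8,
                          male_fraction = 0.34,
                          seed = 1L,
                          mmse_noise_sd = 1.5,
                          train_fraction = 0.7) {
  effect_size <- match.arg(effect_size)
  stopifnot(n_participants >= 2L,
            adrd_prevalence >= 0, adrd_prevalence <= 1,
            mmse_noise_sd >= 0,
            train_fraction > 0, train_fraction < 1)
  structure(list(n_participants = as.integer(n_participants),
                 adrd_prevalence = adrd_prevalence,
                 effect_size = effect_size,
                 age_mean = age_mean, age_sd = age_sd,
                 male_fraction = male_fraction,
                 seed = as.integer(seed),
                 mmse_noise_sd = mmse_noise_sd,
                 train_fraction = train_fraction),
            class = "cohort_config")
}

effect_multiplier <- function(effect_size) {
  switch(effect_size, strong = 1, weak = 0.5, none = 0)
}

# per-participant RNG stream derived from (seed, index): cohorts are
# extensible without reshuffling earlier participants
participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483629)
}

#' Sample an MMSE score from latent severity
#'
#' `MMSE = clamp(round(29 - 22 s + e), 0, 30)` with `e ~ Normal(0, noise_sd)`.
#' The line maps `s = 0` to MMSE 29 (cognitively normal) and `s = 1` to
#' MMSE 7 (severe), so severity spans the CN-to-severe range and MMSE is
#' inversely linked to severity.
#'
#' @param s Latent severity in [0, 1].
#' @param noise_sd Noise SD in MMSE points.
#' @return Integer MMSE in [0, 30].
#' @export
sample_mmse <- function(s, noise_sd = 1.5) {
  if (any(s < 0 | s > 1)) stop("severity s must lie in [0, 1]")
  eps <- if (noise_sd > 0) stats::rnorm(length(s), 0, noise_sd) else 0
  as.integer(pmin(pmax(round(29 - 22 * s + eps), 0), 30))
}

# manipulated category rates as a function of severity; e is the effect
# multiplier (0 for the null). Directions mirror the reported ADRD profile.
category_rates <- function(s, e) {
  c(personal_pronoun   = 0.050 + 0.050 * e * s,
    impersonal_pronoun = 0.050 + 0.070 * e * s,
    adverb             = 0.055 + 0.060 * e * s,
    nonfluency         = 0.015 + 0.050 * e * s,
    filler             = 0.015 + 0.045 * e * s,
    assent             = 0.010 + 0.030 * e * s,
    article            = 0.120 - 0.050 * e * s,
    preposition        = 0.110 - 0.045 * e * s,
    family             = 0.050 - 0.035 * e * s,
    fulfil             = 0.040 - 0.030 * e * s,
    auxiliary_verb     = 0.075,
    conjunction        = 0.050,
    negation           = 0.010)
}

# words emitted when a manipulated category fires; phrases (underscores)
# render as two tokens and are picked up by the bigram matcher
category_emission_words <- function() {
  list(
    personal_pronoun = c("he", "she", "they", "his", "her"),
    impersonal_pronoun = c("it", "that", "this", "something", "everything"),
    adverb = c("there", "just", "really", "very", "now", "then", "again"),
    nonfluency = c("uh", "um", "er", "hm", "oh"),
    filler = c("well", "like", "basically", "actually", "anyway",
               "you_know", "i_mean", "kind_of", "sort_of", "so"),
    assent = c("yeah", "okay", "yes", "alright"),
    article = c("the", "the", "the", "a", "an"),
    preposition = c("in", "on", "of", "with", "under", "from", "into",
                    "beside", "through"),
    family = c("mother", "mom", "sister", "brother", "children", "son",
               "daughter", "family"),
    fulfil = c("enough", "full", "done", "whole", "plenty", "finished",
               "complete"),
    auxiliary_verb = c("is", "was", "are", "has", "have", "had", "will",
                       "can", "would"),
    conjunction = c("and", "but", "because", "while", "when", "or"),
    negation = c("not", "no", "never"))
}

# deterministic content-word pool built from the dictionary's concrete
# categories, excluding anything that matches a manipulated category so that
# manipulated rates stay fully controlled
content_pool <- function(dictionary) {
  src <- c("kitchen", "home", "food", "drink", "nature", "animal", "color",
           "clothing", "body", "adjective", "verb", "motion", "perception",
           "leisure", "work", "physical", "tech", "weatherless")
  words <- character(0)
  for (cat in intersect(src, dictionary$category_order)) {
    for (p in dictionary$categories[[cat]]) {
      if (grepl("_", p, fixed = TRUE)) next
      if (endsWith(p, "*")) {
        stem <- sub("\\*$", "", p)
        words <- c(words, stem, paste0(stem, "s"), paste0(stem, "ing"))
      } else {
        words <- c(words, p)
      }
    }
  }
  words <- sort(unique(words))
  excl <- c("pronoun", "personal_pronoun", "impersonal_pronoun", "adverb",
            "nonfluency", "filler", "assent", "article", "preposition",
            "family", "fulfil", "auxiliary_verb", "conjunction", "negation")
  bad <- rep(FALSE, length(words))
  for (cat in excl) {
    pats <- dictionary$categories[[cat]]
    is_pref <- endsWith(pats, "*")
    bad <- bad | words %in% pats[!is_pref]
    for (stem in sub("\\*$", "", pats[is_pref]))
      bad <- bad | startsWith(words, stem)
  }
  words[!bad]
}

#' Sample a synthetic picture-description transcript
#'
#' Tokens are drawn sentence by sentence: each position either fires one of
#' the manipulated dictionary categories (rates shift monotonically with
#' severity in the seeded directions) or draws a content word from a
#' Zipf-weighted pool whose active size shrinks with severity (lowering
#' CTTR and Honore). Sentence length decreases and the adjacent-duplicate
#' probability increases with severity. With `effect_size = "none"` severity
#' is ignored and all participants share one distribution.
#'
#' @param participant_id Identifier for the resulting [transcript()].
#' @param s Latent severity in [0, 1].
#' @param effect_size `"strong"`, `"weak"` or `"none"`.
#' @param dictionary Category dictionary (default: the bundled stand-in).
#' @param seed Optional integer; when given, the RNG is seeded locally so
#'   the same call reproduces the same transcript.
#' @return A [transcript()] object.
#' @export
sample_transcript <- function(participant_id, s,
                              effect_size = c("strong", "weak", "none"),
                              dictionary = load_dictionary(standin_dictionary_path()),
                              seed = NULL) {
  effect_size <- match.arg(effect_size)
  if (s < 0 || s > 1) stop("severity s must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  e <- effect_multiplier(effect_size)
  rates <- category_rates(s, e)
  emis <- category_emission_words()
  pool <- content_pool(dictionary)
  k <- max(30L, round(length(pool) * (1 - 0.7 * e * s)))
  active <- pool[seq_len(min(k, length(pool)))]
  w <- 1 / seq_along(active)
  cum <- cumsum(rates)
  n_sent <- 3L + stats::rpois(1, 8)
  mean_len <- max(4, 11 - 5 * e * s)
  p_dup <- 0.01 + 0.10 * e * s
  sentences <- character(n_sent)
  for (si in seq_len(n_sent)) {
    len <- max(3L, stats::rpois(1, mean_len))
    toks <- character(0)
    while (length(toks) < len) {
      if (length(toks) > 0L && stats::runif(1) < p_dup) {
        toks <- c(toks, toks[length(toks)])
        next
      }
      u <- stats::runif(1)
      hit <- which(u < cum)
      word <- if (length(hit) > 0L) {
        cat_name <- names(rates)[hit[1L]]
        sample(emis[[cat_name]], 1L)
      } else {
        sample(active, 1L, prob = w)
      }
      toks <- c(toks, strsplit(word, "_", fixed = TRUE)[[1L]])
    }
    sentences[si] <- paste(toks, collapse = " ")
  }
  transcript(participant_id, paste0(paste(sentences, collapse = ". "), "."))
}

#' Generate a full synthetic cohort
#'
#' Draws per-participant latent severities (CN severities below 0.35, ADRD
#' above, so the ADRD class spans mild-to-severe MMSE), demographics, MMSE
#' via [sample_mmse()], transcripts via [sample_transcript()], and a
#' label-stratified train/test split (default 70:30). Each participant has an RNG
#' stream derived from `(seed, index)`, so cohorts are reproducible and
#' extensible.
#'
#' @param config A [cohort_config()].
#' @return List with `transcripts`, `metadata` (participant records) and
#'   `truth` (data.frame of participant_id, severity, true label and the
#'   manipulated per-category target rates).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  n_adrd <- round(n * config$adrd_prevalence)
  if (config$adrd_prevalence > 0 && config$adrd_prevalence < 1 &&
      (n_adrd < 2L || n - n_adrd < 2L))
    stop("cohort too small to hold both diagnosis classes (need >= 2 each); ",
         "increase n_participants")
  dictionary <- load_dictionary(standin_dictionary_path())
  is_adrd <- c(rep(TRUE, n_adrd), rep(FALSE, n - n_adrd))
  ids <- sprintf("p%03d", seq_len(n))
  e <- effect_multiplier(config$effect_size)
  meta <- vector("list", n)
  transcripts <- vector("list", n)
  sev <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(participant_seed(config$seed, i))
    s <- if (is_adrd[i]) {
      0.35 + 0.65 * stats::rbeta(1, 1.1, 1.5)
    } else {
      0.35 * stats::rbeta(1, 1.5, 2.5)
    }
    sev[i] <- s
    mmse <- sample_mmse(s, config$mmse_noise_sd)
    age <- round(stats::rnorm(1, config$age_mean, config$age_sd), 1)
    sex <- if (stats::runif(1) < config$male_fraction) "male" else "female"
    transcripts[[i]] <- sample_transcript(ids[i], s, config$effect_size,
                                          dictionary = dictionary)
    meta[[i]] <- data.frame(participant_id = ids[i], age = age, sex = sex,
                            mmse = mmse,
                            diagnosis = if (is_adrd[i]) "ADRD" else "CN",
                            split = NA_character_, language = "en",
                            stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta)
  # stratified 70:30 split, shuffled within label from the master seed
  set.seed(participant_seed(config$seed, 0L))
  metadata$split <- "test"
  for (lab in unique(metadata$diagnosis)) {
    idx <- which(metadata$diagnosis == lab)
    idx <- sample(idx)
    n_train <- round(config$train_fraction * length(idx))
    metadata$split[idx[seq_len(n_train)]] <- "train"
  }
  rates <- t(vapply(sev, function(s) category_rates(s, e),
                    category_rates(0, 0)))
  truth <- data.frame(participant_id = ids, severity = sev,
                      label = ifelse(sev > 0.35, "ADRD", "CN"),
                      rates, stringsAsFactors = FALSE)
  list(transcripts = transcripts, metadata = metadata, truth = truth)
}

#' Binary impairment labels from an MMSE cutoff
#'
#' Labels a participant impaired iff `MMSE <= cutoff` (default 26, the
#' standard screening cutoff; MMSE 26 itself falls in the MCI interval and
#' is impaired).
#'
#' @param records data.frame with `participant_id` and `mmse` columns.
#' @param cutoff MMSE cutoff (default 26).
#' @return Logical vector, TRUE = impaired.
#' @export
label_from_mmse <- function(records, cutoff = 26) {
  miss <- is.na(records$mmse)
  if (any(miss))
    stop("mmse missing for participant(s): ",
         paste(records$participant_id[miss], collapse = ", "))
  records$mmse <= cutoff
}
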