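#' Token, type and hapax counts
#'
#' @param tokens Character vector of word tokens.
#' @return List with `n_tokens` (N), `n_types` (V) and `n_hapax` (V1, types
#'   occurring exactly once). Always `V1 <= V <= N`.
#' @export
lexical_counts <- function(tokens) {
  tab <- table(tokens)
  list(n_tokens = length(tokens),
       n_types = length(tab),
       n_hapax = sum(tab == 1L))
}

#' Corrected type-token ratio (CTTR)
#'
#' Carroll's length-corrected type-token ratio, `V / sqrt(2 N)`. Unlike the
#' plain TTR it does not collapse toward zero as transcripts get longer,
#' making it comparable across picture descriptions of different durations.
#' Higher values indicate richer vocabulary.
#'
#' @param counts List as from [lexical_counts()].
#' @return Positive numeric scalar.
#' @export
corrected_ttr <- function(counts) {
  if (counts$n_tokens < 1L) stop("empty transcript: CTTR undefined for N = 0")
  counts$n_types / sqrt(2 * counts$n_tokens)
}

#' Brunet's index (W)
#'
#' `W = N ^ (V ^ -0.165)` with the classical constant 0.165. Lower values
#' indicate richer vocabulary; for fixed N, W strictly decreases in V.
#'
#' @inheritParams corrected_ttr
#' @return Numeric scalar `>= 1`.
#' @export
brunet_index <- function(counts) {
  if (counts$n_tokens < 1L || counts$n_types < 1L)
    stop("empty transcript: Brunet index undefined for N = 0")
  counts$n_tokens ^ (counts$n_types ^ (-0.165))
}

#' Honore's statistic (R)
#'
#' `R = 100 * ln(N) / (1 - V1/V)` where V1 is the hapax count. Higher values
#' indicate richer vocabulary. When every type is a hapax (V1 = V) the
#' denominator vanishes; it is floored at `1/(2V)`, which caps R at
#' `200 * V * ln(N)` instead of returning infinity.
#'
#' @inheritParams corrected_ttr
#' @return Finite non-negative numeric scalar.
#' @export
honore_index <- function(counts) {
  if (counts$n_tokens < 1L || counts$n_types < 1L)
    stop("empty transcript: Honore index undefined for N = 0")
  denom <- max(1 - counts$n_hapax / counts$n_types, 1 / (2 * counts$n_types))
  100 * log(counts$n_tokens) / denom
}

#' Propositional idea density
#'
#' Proportion of proposition-bearing tokens — those tagged VERB, ADJ, ADV,
#' ADP or CONJ — among all tokens. Operationalizes idea density as a
#' POS-tag proportion.
#'
#' @param tokens Character vector of tokens.
#' @param pos_tags Character vector of tags aligned 1:1 with `tokens`
#'   (default: [pos_tag()] output).
#' @return Numeric scalar in [0, 1].
#' @export
idea_density <- function(tokens, pos_tags = pos_tag(tokens)) {
  if (length(tokens) < 1L) stop("empty transcript: idea density undefined")
  if (length(pos_tags) != length(tokens))
    stop("pos_tags length (", length(pos_tags),
         ") does not match tokens length (", length(tokens), ")")
  mean(pos_tags %in% proposition_tags())
}

#' Count of consecutive duplicate words
#'
#' Number of positions i > 1 with `tokens[i] == tokens[i-1]`; a simple
#' perseveration marker ("the the boy").
#'
#' @param tokens Character vector of tokens.
#' @return Non-negative integer.
#' @export
consecutive_duplicates <- function(tokens) {
  n <- length(tokens)
  if (n < 2L) return(0L)
  sum(tokens[-1L] == tokens[-n])
}

#' Dictionary category proportions
#'
#' For every category in the dictionary, the fraction of tokens matching any
#' of its patterns. A token may match multiple categories. Prefix patterns
#' (`know*`) match any token starting with the stem; underscore bigrams
#' (`you_know`) are matched against adjacent token pairs and counted against
#' N like single-token matches.
#'
#' @param tokens Character vector of tokens.
#' @param dictionary A `category_dictionary` from [load_dictionary()].
#' @return Named numeric vector (dictionary category order), each in [0, 1].
#'   An empty token vector yields all zeros with a warning.
#' @export
category_proportions <- function(tokens, dictionary) {
  stopifnot(inherits(dictionary, "category_dictionary"))
  cats <- dictionary$category_order
  out <- stats::setNames(numeric(length(cats)), cats)
  n <- length(tokens)
  if (n == 0L) {
    warning("empty token stream: all category proportions set to 0")
    return(out)
  }
  uni_tab <- table(tokens)
  uni_types <- names(uni_tab)
  bi_tab <- if (n >= 2L) {
    table(paste(tokens[-n], tokens[-1L], sep = "_"))
  } else table(character(0))
  bi_types <- names(bi_tab)
  for (cat in cats) {
    pats <- dictionary$categories[[cat]]
    if (length(pats) == 0L) next
    is_bigram <- grepl("_", pats, fixed = TRUE)
    count <- match_pattern_count(pats[!is_bigram], uni_tab, uni_types) +
      match_pattern_count(pats[is_bigram], bi_tab, bi_types)
    out[[cat]] <- count / n
  }
  out
}

# total frequency of types matched by a pattern set (literal or prefix)
match_pattern_count <- function(pats, type_tab, types) {
  if (length(pats) == 0L || length(types) == 0L) return(0)
  is_prefix <- endsWith(pats, "*")
  matched <- types %in% pats[!is_prefix]
  for (stem in sub("\\*$", "", pats[is_prefix])) {
    matched <- matched | startsWith(types, stem)
  }
  sum(type_tab[matched])
}

#' Raw disfluency aggregate
#'
#' Sum of the nonfluency ("uh", "um"), filler ("you know", "so") and assent
#' ("yeah", "ok") category proportions. The reported feature is the cohort
#' z-score of this raw sum (applied in [extract_cohort_features()]); a
#' zero-variance cohort z-scores to 0.
#'
#' @param props Named category-proportion vector containing `nonfluency`,
#'   `filler` and `assent`.
#' @return Numeric scalar (raw, before z-scoring).
#' @export
disfluency_raw <- function(props) {
  need <- c("nonfluency", "filler", "assent")
  absent <- setdiff(need, names(props))
  if (length(absent) > 0L)
    stop("disfluency aggregate needs missing categor",
         if (length(absent) > 1L) "ies: " else "y: ",
         paste(absent, collapse = ", "))
  sum(props[need])
}

#' Analytic-thinking composite
#'
#' Categorical-dynamic style composite over eight function-word categories,
#' with inputs expressed as percentages of tokens:
#' `30 + article + preposition - personal_pronoun - impersonal_pronoun -
#' auxiliary_verb - conjunction - adverb - negation`, clamped to [0, 100].
#' Higher values indicate more categorical/analytic language; narrative,
#' dynamic language scores low.
#'
#' @param props Named category-proportion vector (fractions in [0, 1])
#'   containing the eight input categories.
#' @return Numeric scalar in [0, 100].
#' @export
analytic_composite <- function(props) {
  pos <- c("article", "preposition")
  neg <- c("personal_pronoun", "impersonal_pronoun", "auxiliary_verb",
           "conjunction", "adverb", "negation")
  absent <- setdiff(c(pos, neg), names(props))
  if (length(absent) > 0L)
    stop("analytic composite needs missing categories: ",
         paste(absent, collapse = ", "))
  raw <- 30 + 100 * (sum(props[pos]) - sum(props[neg]))
  min(max(raw, 0), 100)
}

#' Mean words per sentence
#'
#' @param x A [transcript()] object.
#' @return `N / number of sentences`.
#' @export
words_per_sentence <- function(x) {
  stopifnot(inherits(x, "transcript"))
  if (nrow(x$sentences) == 0L)
    stop("empty transcript '", x$participant_id,
         "': words per sentence undefined")
  length(x$tokens) / nrow(x$sentences)
}

#' Canonical feature schema
#'
#' Fixed feature order: the five lexical-semantic indices, words per
#' sentence, the analytic composite, the disfluency aggregate, then one
#' proportion per dictionary category in dictionary order. With the bundled
#' 92-category dictionary this is exactly 100 features.
#'
#' @param dictionary A `category_dictionary`.
#' @return data.frame with columns `name` and `group`
#'   ({lexical, structural, composite, category}).
#' @export
feature_schema <- function(dictionary) {
  stopifnot(inherits(dictionary, "category_dictionary"))
  fixed <- data.frame(
    name = c("cttr", "brunet_w", "honore_r", "idea_density",
             "consecutive_duplicates", "words_per_sentence",
             "analytic_thinking", "disfluency"),
    group = c(rep("lexical", 5L), "structural", "composite", "composite"))
  rbind(fixed, data.frame(name = dictionary$category_order,
                          group = "category"))
}

#' Write the canonical feature order as a JSON schema
#'
#' @param dictionary A `category_dictionary`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_feature_schema <- function(dictionary, path) {
  sc <- feature_schema(dictionary)
  jsonlite::write_json(list(n_features = nrow(sc), features = sc), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Extract the interpretable feature vector from one transcript
#'
#' Computes all per-transcript features in the canonical order of
#' [feature_schema()]. The disfluency slot holds the raw aggregate; the
#' cohort z-score is applied by [extract_cohort_features()], since a
#' normalisation constant cannot be defined from a single transcript.
#'
#' @param x A [transcript()] object with at least one token.
#' @param dictionary A `category_dictionary`.
#' @return Named numeric vector (length `8 + n categories`; 100 with the
#'   bundled dictionary), with a `groups` attribute.
#' @export
extract_features <- function(x, dictionary) {
  stopifnot(inherits(x, "transcript"))
  if (length(x$tokens) == 0L)
    stop("empty transcript for participant '", x$participant_id,
         "': no features can be extracted")
  counts <- lexical_counts(x$tokens)
  props <- category_proportions(x$tokens, dictionary)
  vals <- c(
    cttr = corrected_ttr(counts),
    brunet_w = brunet_index(counts),
    honore_r = honore_index(counts),
    idea_density = idea_density(x$tokens),
    consecutive_duplicates = as.numeric(consecutive_duplicates(x$tokens)),
    words_per_sentence = words_per_sentence(x),
    analytic_thinking = analytic_composite(props),
    disfluency = disfluency_raw(props))
  out <- c(vals, props)
  sc <- feature_schema(dictionary)
  stopifnot(identical(names(out), sc$name))
  attr(out, "groups") <- sc$group
  out
}

#' Extract the cohort feature matrix
#'
#' Applies [extract_features()] to every transcript and z-scores the
#' disfluency column across the cohort (zero variance maps to 0), producing
#' the normalised disfluency aggregate.
#'
#' @param transcripts List of [transcript()] objects.
#' @param dictionary A `category_dictionary`.
#' @return data.frame: `participant_id`, then the feature columns in
#'   canonical order.
#' @export
extract_cohort_features <- function(transcripts, dictionary) {
  stopifnot(length(transcripts) > 0L)
  rows <- lapply(transcripts, extract_features, dictionary = dictionary)
  mat <- do.call(rbind, rows)
  d <- mat[, "disfluency"]
  sdd <- stats::sd(d)
  mat[, "disfluency"] <- if (length(d) > 1L && sdd > 0) {
    (d - mean(d)) / sdd
  } else 0
  out <- data.frame(
    participant_id = vapply(transcripts, function(x) x$participant_id, ""),
    mat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
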