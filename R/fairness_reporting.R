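#' Per-subgroup classification performance
#'
#' Computes the classification metric set within each level of a grouping
#' variable (sex, median-split age band, MMSE severity group, ...). Groups
#' smaller than `min_size` are reported with a `flagged` marker rather than
#' silently dropped.
#'
#' @param labels True labels (logical/0-1).
#' @param scores Predicted probabilities.
#' @param groups Group membership vector, no missing values.
#' @param threshold Classification threshold (default 0.5).
#' @param min_size Minimum group size before flagging (default 10).
#' @return data.frame: one row per group with n, sensitivity, specificity,
#'   roc_auc, accuracy, positive_rate and `flagged`.
#' @export
subgroup_performance <- function(labels, scores, groups,
                                 threshold = 0.5, min_size = 10L) {
  stopifnot(length(labels) == length(scores),
            length(labels) == length(groups))
  if (length(groups) == 0L || any(is.na(groups)))
    stop("every sample needs a non-missing group")
  labels <- as.logical(labels)
  pred <- scores > threshold
  lv <- unique(groups)
  rows <- lapply(lv, function(g) {
    in_g <- groups == g
    m <- classification_metrics(labels[in_g], pred[in_g], scores[in_g])
    data.frame(group = g, n = sum(in_g),
               sensitivity = m$sensitivity, specificity = m$specificity,
               roc_auc = m$roc_auc, accuracy = m$accuracy,
               positive_rate = mean(pred[in_g]),
               flagged = sum(in_g) < min_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Demographic parity gap
#'
#' Maximum over group pairs of the absolute difference in positive
#' prediction rates. Zero means perfectly equal positive-prediction rates
#' across groups (demographic parity).
#'
#' @param predicted_labels Logical/0-1 predicted labels.
#' @param groups Group membership vector (>= 2 distinct groups).
#' @return Gap in [0, 1].
#' @export
demographic_parity_gap <- function(predicted_labels, groups) {
  stopifnot(length(predicted_labels) == length(groups))
  if (any(is.na(groups))) stop("groups must be non-missing")
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need at least 2 groups for a parity gap")
  rates <- vapply(lv, function(g) mean(as.logical(predicted_labels[groups == g])), 0)
  max(stats::dist(rates))
}

#' Equalized-odds style gaps
#'
#' Maximum pairwise absolute difference in group sensitivities and in group
#' specificities (fraction scale); reported alongside demographic parity
#' since screening models should hold error rates, not just positive rates,
#' level across groups.
#'
#' @inheritParams subgroup_performance
#' @return List with `sensitivity_gap` and `specificity_gap` (NA when a
#'   group lacks the relevant class).
#' @export
equalized_odds_gaps <- function(labels, scores, groups, threshold = 0.5) {
  tab <- subgroup_performance(labels, scores, groups, threshold,
                              min_size = 0L)
  gap <- function(v) if (any(is.na(v))) NA_real_ else
    max(stats::dist(v / 100))
  list(sensitivity_gap = gap(tab$sensitivity),
       specificity_gap = gap(tab$specificity))
}

#' Predicted-probability profile across severity groups
#'
#' Groups participants by MMSE severity band ([mmse_to_group()]) and
#' reports the mean, SD and count of predicted probabilities per band,
#' together with the Spearman correlation between score and MMSE. In a
#' well-calibrated screening model the mean predicted probability rises
#' monotonically from CN through MCI and moderate to severe, and the
#' score-MMSE correlation is negative.
#'
#' @param scores Predicted probabilities.
#' @param mmse Integer MMSE scores in [0, 30].
#' @return List with `profile` (data.frame ordered severe, moderate, MCI,
#'   CN) and `spearman` (list r, p, n from [spearman_rank()]).
#' @export
probability_severity_profile <- function(scores, mmse) {
  if (length(scores) == 0L) stop("empty input: no scores to profile")
  stopifnot(length(scores) == length(mmse))
  grp <- mmse_to_group(mmse)
  order_levels <- c("severe", "moderate", "MCI", "CN")
  present <- order_levels[order_levels %in% grp]
  profile <- do.call(rbind, lapply(present, function(g) {
    s <- scores[grp == g]
    data.frame(group = g, mean = mean(s),
               sd = if (length(s) > 1L) stats::sd(s) else NA_real_,
               n = length(s), stringsAsFactors = FALSE)
  }))
  rownames(profile) <- NULL
  list(profile = profile, spearman = spearman_rank(scores, mmse))
}

#' Median-split age bands
#'
#' @param age Numeric ages.
#' @return Character vector "younger"/"older" split at the cohort median
#'   (ties at the median go to "younger").
#' @export
age_band <- function(age) {
  med <- stats::median(age)
  ifelse(age <= med, "younger", "older")
}
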