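#' ROC area under the curve
#'
#' Probability that a randomly chosen positive case receives a higher score
#' than a randomly chosen negative case, with ties counting one half.
#' Computed via the rank (Mann-Whitney) identity, which is exactly the
#' pairwise concordance.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 vector, TRUE/1 = positive.
#' @return AUC on [0, 1]; `NA` if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/n and
#' ROC-AUC, all reported in percent. With a single-class truth vector the
#' undefined entries (sensitivity or specificity, and AUC) are returned as
#' `NA` and flagged in the `undefined` field rather than propagating NaN.
#'
#' @param labels True labels (logical or 0/1; TRUE = positive/ADRD).
#' @param predicted_labels Predicted labels, same coding.
#' @param scores Numeric scores for AUC (optional; `NULL` skips AUC).
#' @return List with `sensitivity`, `specificity`, `accuracy`, `roc_auc`
#'   (percent) and `undefined` (character vector of unavailable metrics).
#' @export
classification_metrics <- function(labels, predicted_labels, scores = NULL) {
  labels <- as.logical(labels)
  predicted_labels <- as.logical(predicted_labels)
  stopifnot(length(labels) >= 1L,
            length(labels) == length(predicted_labels))
  tp <- sum(labels & predicted_labels)
  fn <- sum(labels & !predicted_labels)
  tn <- sum(!labels & !predicted_labels)
  fp <- sum(!labels & predicted_labels)
  undefined <- character(0)
  sens <- if (tp + fn > 0L) 100 * tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (tn + fp > 0L) 100 * tn / (tn + fp) else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  auc <- if (is.null(scores)) NA_real_ else 100 * roc_auc(scores, labels)
  if (!is.null(scores) && is.na(auc)) undefined <- c(undefined, "roc_auc")
  list(sensitivity = sens, specificity = spec,
       accuracy = 100 * (tp + tn) / length(labels),
       roc_auc = auc, undefined = undefined)
}

#' Regression error metrics
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return List with `mae` (mean absolute error) and `rmse` (root mean
#'   square error); always `rmse >= mae`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) == 0L) stop("empty input: regression metrics undefined")
  stopifnot(length(y) == length(yhat))
  err <- y - yhat
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (ties averaged), with a two-sided
#' p-value from the t approximation `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r`, `p` and `n`. Zero variance in either ranked
#'   vector yields `r = NA` with `p = NA` (flagged undefined).
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  r <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}
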