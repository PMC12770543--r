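#' Traffic-light risk thresholds
#'
#' Zone boundaries on the predicted ADRD probability, following interval
#' notation: Green `[0, t_low]`, Amber `(t_low, t_high]`, Red `(t_high, 1]`.
#' The reference operating point from validation-set search is
#' `t_low = 0.45`, `t_high = 0.65`.
#'
#' @param t_low,t_high Probabilities with `0 <= t_low <= t_high <= 1`.
#' @return A `risk_thresholds` object.
#' @export
risk_thresholds <- function(t_low, t_high) {
  stopifnot(t_low >= 0, t_high <= 1, t_low <= t_high)
  structure(list(t_low = t_low, t_high = t_high), class = "risk_thresholds")
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat(sprintf("<risk thresholds: Green [0, %.2f], Amber (%.2f, %.2f], Red (%.2f, 1]>\n",
              x$t_low, x$t_low, x$t_high, x$t_high))
  invisible(x)
}

#' Assign traffic-light risk zones
#'
#' Green iff `score <= t_low`; Amber iff `t_low < score <= t_high`; Red iff
#' `score > t_high`. Boundary scores belong to the lower-risk zone (a score
#' exactly at 0.45 is Green under the reference thresholds, and 0.65 is
#' Amber).
#'
#' @param score Probabilities in [0, 1] (vectorized).
#' @param thresholds A [risk_thresholds()].
#' @return Character vector in {"Green", "Amber", "Red"}.
#' @export
assign_risk <- function(score, thresholds) {
  stopifnot(inherits(thresholds, "risk_thresholds"))
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("risk scores must lie in [0, 1]")
  ifelse(score <= thresholds$t_low, "Green",
         ifelse(score <= thresholds$t_high, "Amber", "Red"))
}

#' Youden's J statistic
#'
#' `J = sensitivity + specificity - 1`, on the fraction scale.
#'
#' @param sensitivity,specificity Fractions in [0, 1].
#' @return J in [-1, 1].
#' @export
youden_j <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  sensitivity + specificity - 1
}

#' Selective (Amber-excluded) classification metrics
#'
#' Implements the selective-classification reading of the traffic-light
#' scheme: Amber cases (model uncertainty) are abstained from; retained
#' Green cases are predicted negative (low risk) and Red cases positive
#' (high risk). Metrics are computed on the retained set only; coverage is
#' the retained fraction.
#'
#' @param scores Probabilities in [0, 1].
#' @param labels Logical/0-1 true labels (TRUE = ADRD).
#' @param thresholds A [risk_thresholds()].
#' @return List with `coverage`, `n_retained`, `zones` (per-sample zone),
#'   `metrics` (percent, as [classification_metrics()]) and `youden_j`
#'   (fraction scale; `NA` if sensitivity or specificity is undefined).
#' @export
selective_metrics <- function(scores, labels, thresholds) {
  stopifnot(length(scores) == length(labels))
  zones <- assign_risk(scores, thresholds)
  keep <- zones != "Amber"
  if (!any(keep))
    stop("all scores fall in the Amber zone: no retained predictions")
  labels <- as.logical(labels)
  pred <- zones[keep] == "Red"
  m <- classification_metrics(labels[keep], pred, scores[keep])
  j <- if (is.na(m$sensitivity) || is.na(m$specificity)) NA_real_ else
    youden_j(m$sensitivity / 100, m$specificity / 100)
  list(coverage = mean(keep), n_retained = sum(keep), zones = zones,
       metrics = m, youden_j = j)
}

#' Grid search for traffic-light thresholds
#'
#' Exhaustively enumerates all grid pairs `t_low <= t_high` at the given
#' resolution on validation scores (out-of-fold predictions), drops pairs
#' with coverage below `min_coverage` or with undefined retained metrics,
#' and ranks the rest lexicographically by retained Youden's J, then
#' retained ROC-AUC, then coverage. Exact objective ties resolve to the
#' smaller `(t_low, t_high)` pair, preferring narrower, lower thresholds to
#' prevent overfitting on small validation sets.
#'
#' @param val_scores Validation probabilities in [0, 1].
#' @param val_labels Validation labels.
#' @param resolution Grid step (default 0.05).
#' @param min_coverage Minimum retained fraction (default 0.5).
#' @return List with `thresholds` (a [risk_thresholds()]) and `trace`, the
#'   full table of feasible grid pairs and their retained metrics.
#' @export
grid_search_thresholds <- function(val_scores, val_labels,
                                   resolution = 0.05, min_coverage = 0.5) {
  stopifnot(resolution > 0, resolution <= 1)
  val_labels <- as.logical(val_labels)
  if (length(unique(val_labels)) < 2L)
    stop("threshold search needs both classes in the validation labels")
  grid <- seq(0, 1, by = resolution)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  rows <- list()
  for (tl in grid) for (th in grid[grid >= tl]) {
    thr <- risk_thresholds(tl, th)
    res <- tryCatch(selective_metrics(val_scores, val_labels, thr),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (res$coverage < min_coverage) next
    if (is.na(res$youden_j) || is.na(res$metrics$roc_auc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      t_low = tl, t_high = th, coverage = res$coverage,
      youden_j = res$youden_j, roc_auc = res$metrics$roc_auc,
      sensitivity = res$metrics$sensitivity,
      specificity = res$metrics$specificity,
      accuracy = res$metrics$accuracy)
  }
  if (length(rows) == 0L)
    stop("no feasible threshold pair at resolution ", resolution,
         " with min_coverage ", min_coverage)
  trace <- do.call(rbind, rows)
  ord <- order(-trace$youden_j, -trace$roc_auc, -trace$coverage,
               trace$t_low, trace$t_high)
  trace <- trace[ord, ]
  rownames(trace) <- NULL
  list(thresholds = risk_thresholds(trace$t_low[1], trace$t_high[1]),
       trace = trace)
}
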