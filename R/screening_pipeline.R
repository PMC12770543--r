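#' Model specification for the screening forests
#'
#' Defaults pin the hyperparameters selected for the two tasks: the ADRD
#' detector is a Random Forest of 50 trees with maximum depth 16; the MMSE
#' severity regressor is a Random Forest with a minimum of two samples per
#' leaf. Forest internals (feature subsampling, impurity) follow the ranger
#' defaults and are recorded in run manifests.
#'
#' @param task `"detect"` (probability forest for ADRD) or `"severity"`
#'   (regression forest for MMSE).
#' @param n_trees Number of trees (default 50).
#' @param max_depth Maximum tree depth; `NULL` = unlimited. Default 16 for
#'   detect, unlimited for severity.
#' @param min_samples_leaf Minimum samples per leaf. Default 1 for detect,
#'   2 for severity.
#' @param seed Integer seed; all fits are single-threaded and deterministic.
#' @return A `model_spec` list.
#' @export
model_spec <- function(task = c("detect", "severity"),
                       n_trees = 50L,
                       max_depth = if (task == "detect") 16L else NULL,
                       min_samples_leaf = if (task == "detect") 1L else 2L,
                       seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_trees >= 1L, is.null(max_depth) || max_depth >= 1L,
            min_samples_leaf >= 1L)
  structure(list(task = task, n_trees = as.integer(n_trees),
                 max_depth = if (is.null(max_depth)) 0L else
                   as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 seed = as.integer(seed)),
            class = "model_spec")
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    if (names(features)[1] == "participant_id")
      features <- features[, -1, drop = FALSE]
    features <- as.matrix(features)
  }
  stopifnot(is.numeric(features))
  features
}

#' Fit a screening forest
#'
#' @param features Numeric feature matrix or data.frame (a leading
#'   `participant_id` column is dropped automatically).
#' @param y For `detect`: logical/0-1 labels (TRUE = ADRD). For `severity`:
#'   numeric MMSE scores.
#' @param spec A [model_spec()].
#' @param seed Optional seed overriding `spec$seed` for this fit (used by
#'   cross-validation and bootstrap repeats).
#' @return A `screening_model` with the fitted ranger forest, the spec and
#'   the training feature order.
#' @export
fit_screening_model <- function(features, y, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "model_spec"))
  x <- feature_matrix(features)
  stopifnot(nrow(x) == length(y))
  d <- as.data.frame(x)
  if (spec$task == "detect") {
    y <- as.logical(y)
    if (length(unique(y)) < 2L)
      stop("detect task needs both classes in the training labels")
    d$.outcome <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
    fit <- ranger::ranger(
      dependent.variable.name = ".outcome", data = d,
      num.trees = spec$n_trees, max.depth = spec$max_depth,
      min.node.size = spec$min_samples_leaf, probability = TRUE,
      keep.inbag = TRUE, seed = seed, num.threads = 1)
  } else {
    d$.outcome <- as.numeric(y)
    fit <- ranger::ranger(
      dependent.variable.name = ".outcome", data = d,
      num.trees = spec$n_trees, max.depth = spec$max_depth,
      min.node.size = spec$min_samples_leaf,
      keep.inbag = TRUE, seed = seed, num.threads = 1)
  }
  structure(list(fit = fit, spec = spec, feature_names = colnames(x),
                 train_x = x, train_y = y),
            class = "screening_model")
}

#' Predict with a screening model
#'
#' @param model A `screening_model`.
#' @param features Feature matrix/data.frame with the training columns.
#' @return For detect: positive-class probabilities in [0, 1]; for
#'   severity: predicted MMSE.
#' @export
predict_screening <- function(model, features) {
  stopifnot(inherits(model, "screening_model"))
  x <- feature_matrix(features)
  if (!identical(colnames(x), model$feature_names))
    stop("feature columns do not match the training order; expected ",
         length(model$feature_names), " canonical columns")
  p <- stats::predict(model$fit, data = as.data.frame(x),
                      num.threads = 1)$predictions
  if (model$spec$task == "detect") p[, "pos"] else p
}

#' Stratified cross-validation
#'
#' K-fold cross-validation (default 10), stratified by label for the detect
#' task. Every sample is scored exactly once out-of-fold; fold metrics are
#' summarised as mean (SD) across folds. Deterministic given `spec$seed`.
#'
#' @param features Feature matrix/data.frame.
#' @param y Labels (detect) or MMSE (severity).
#' @param spec A [model_spec()].
#' @param k Number of folds (default 10).
#' @return List with `fold_metrics` (data.frame, one row per fold),
#'   `summary` (mean and SD per metric), `oof_scores` (out-of-fold score per
#'   sample, input order) and `fold_id`.
#' @export
cross_validate <- function(features, y, spec, k = 10L) {
  x <- feature_matrix(features)
  n <- nrow(x)
  if (n < k) stop("n (", n, ") < k (", k, "): reduce k")
  set.seed(spec$seed)
  if (spec$task == "detect") {
    yl <- as.logical(y)
    min_class <- min(table(yl))
    if (min_class < k)
      stop("smallest class has ", min_class, " members, fewer than k = ", k,
           "; use a smaller k")
    ord <- c(sample(which(yl)), sample(which(!yl)))
  } else {
    ord <- sample(n)
  }
  fold_id <- integer(n)
  fold_id[ord] <- rep_len(seq_len(k), n)
  oof <- numeric(n)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- fold_id == f
    m <- fit_screening_model(x[!hold, , drop = FALSE], y[!hold], spec,
                             seed = spec$seed + f)
    sc <- predict_screening(m, x[hold, , drop = FALSE])
    oof[hold] <- sc
    rows[[f]] <- if (spec$task == "detect") {
      cm <- classification_metrics(y[hold], sc > 0.5, sc)
      data.frame(fold = f, sensitivity = cm$sensitivity,
                 specificity = cm$specificity, roc_auc = cm$roc_auc,
                 accuracy = cm$accuracy)
    } else {
      rm <- regression_metrics(y[hold], sc)
      data.frame(fold = f, mae = rm$mae, rmse = rm$rmse)
    }
  }
  fold_metrics <- do.call(rbind, rows)
  mets <- setdiff(names(fold_metrics), "fold")
  summary <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(fold_metrics[[m]], na.rm = TRUE), 0),
    sd = vapply(mets, function(m) stats::sd(fold_metrics[[m]]), 0),
    row.names = NULL)
  list(fold_metrics = fold_metrics, summary = summary, oof_scores = oof,
       fold_id = fold_id, n_folds = k, provenance = "cv")
}

#' Bootstrap evaluation on a fixed test set
#'
#' For each of B repeats (default 10): resample the training set with
#' replacement (same size), refit, and evaluate on the fixed, never
#' resampled test set. Reports the mean and a 95% interval
#' `mean +/- 1.96 SD` across repeats, summarising performance variability.
#'
#' @param train_x,train_y Training features and outcomes.
#' @param test_x,test_y Fixed test features and outcomes.
#' @param spec A [model_spec()].
#' @param B Number of bootstrap repeats (default 10).
#' @return List with `repeats` (per-repeat metric rows), `summary`
#'   (metric, mean, lower, upper), `test_scores` (B x n_test matrix of
#'   test-set scores), `n_repeats` and provenance.
#' @export
bootstrap_test_evaluation <- function(train_x, train_y, test_x, test_y,
                                      spec, B = 10L) {
  stopifnot(B >= 2L)
  train_x <- feature_matrix(train_x)
  test_x <- feature_matrix(test_x)
  rows <- vector("list", B)
  scores <- matrix(NA_real_, B, nrow(test_x))
  for (b in seq_len(B)) {
    set.seed(spec$seed + 1000L * b)
    idx <- sample(nrow(train_x), replace = TRUE)
    if (spec$task == "detect") {
      tries <- 0L
      while (length(unique(as.logical(train_y[idx]))) < 2L) {
        tries <- tries + 1L
        if (tries > 50L)
          stop("bootstrap resampling produced single-class training samples ",
               "50 times in a row; training set too imbalanced")
        idx <- sample(nrow(train_x), replace = TRUE)
      }
    }
    m <- fit_screening_model(train_x[idx, , drop = FALSE], train_y[idx],
                             spec, seed = spec$seed + b)
    sc <- predict_screening(m, test_x)
    scores[b, ] <- sc
    rows[[b]] <- if (spec$task == "detect") {
      cm <- classification_metrics(test_y, sc > 0.5, sc)
      data.frame(repeat_id = b, sensitivity = cm$sensitivity,
                 specificity = cm$specificity, roc_auc = cm$roc_auc,
                 accuracy = cm$accuracy)
    } else {
      rm <- regression_metrics(test_y, sc)
      data.frame(repeat_id = b, mae = rm$mae, rmse = rm$rmse)
    }
  }
  repeats <- do.call(rbind, rows)
  mets <- setdiff(names(repeats), "repeat_id")
  mu <- vapply(mets, function(m) mean(repeats[[m]]), 0)
  sdv <- vapply(mets, function(m) stats::sd(repeats[[m]]), 0)
  summary <- data.frame(metric = mets, mean = mu,
                        lower = mu - 1.96 * sdv, upper = mu + 1.96 * sdv,
                        row.names = NULL)
  list(repeats = repeats, summary = summary, test_scores = scores,
       n_repeats = B, provenance = "bootstrap")
}

#' Calibration curve
#'
#' Bins predicted probabilities into `n_bins` equal-width bins on [0, 1]
#' and reports, per non-empty bin, the mean score, the observed event rate
#' and the count. Bin counts sum to `length(scores)`.
#'
#' @param scores Probabilities in [0, 1].
#' @param labels Logical/0-1 outcomes.
#' @param n_bins Number of equal-width bins (>= 2, default 10).
#' @return data.frame with `mean_score`, `event_rate`, `n` per bin.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  stopifnot(n_bins >= 2L, length(scores) == length(labels))
  if (any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1] for calibration binning")
  labels <- as.logical(labels)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(scores, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    in_bin <- bin == b
    data.frame(bin = b, mean_score = mean(scores[in_bin]),
               event_rate = mean(labels[in_bin]), n = sum(in_bin))
  }))
  rownames(out) <- NULL
  out
}

#' Map MMSE to cognitive severity group
#'
#' Intervals follow the standard severity grouping: CN (26, 30],
#' MCI (20, 26], moderate dementia [10, 20], severe dementia [0, 10).
#' Note the boundary conventions: MMSE 26 is MCI, 20 and 10 are both
#' moderate, 9 is severe.
#'
#' @param mmse Integer vector in [0, 30].
#' @return Character vector in {"CN", "MCI", "moderate", "severe"}.
#' @export
mmse_to_group <- function(mmse) {
  if (any(is.na(mmse)) || any(mmse < 0 | mmse > 30))
    stop("mmse must lie in [0, 30] and be non-missing")
  ifelse(mmse > 26, "CN",
         ifelse(mmse > 20, "MCI",
                ifelse(mmse >= 10, "moderate", "severe")))
}
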