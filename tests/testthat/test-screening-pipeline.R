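# brute-force pairwise concordance AUC (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

test_that("classification metrics reproduce confusion-count arithmetic", {
  labels <- c(rep(TRUE, 10), rep(FALSE, 10))
  pred <- c(rep(TRUE, 7), rep(FALSE, 3), rep(FALSE, 8), rep(TRUE, 2))
  m <- classification_metrics(labels, pred)
  expect_equal(m$sensitivity, 70)
  expect_equal(m$specificity, 80)
  expect_equal(m$accuracy, 75)

  sep <- classification_metrics(labels, pred, c(seq(0.6, 0.9, length.out = 10),
                                                seq(0.1, 0.4, length.out = 10)))
  expect_equal(sep$roc_auc, 100)
  tie <- classification_metrics(labels, pred, rep(0.5, 20))
  expect_equal(tie$roc_auc, 50)

  one_class <- classification_metrics(rep(TRUE, 5), rep(TRUE, 5), runif(5))
  expect_true(is.na(one_class$specificity))
  expect_setequal(one_class$undefined, c("specificity", "roc_auc"))
  expect_equal(one_class$accuracy, 100)
})

test_that("ROC-AUC equals brute-force pairwise concordance on random sets", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("regression metrics satisfy their identities", {
  m <- regression_metrics(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(m$mae, 1.5)
  expect_equal(m$rmse, sqrt(2.5), tolerance = 1e-12)
  expect_equal(regression_metrics(1:5, 1:5), list(mae = 0, rmse = 0))
  m1 <- regression_metrics(3, 0)
  expect_equal(m1$mae, 3); expect_equal(m1$rmse, 3)
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(30); yh <- rnorm(30)
    m <- regression_metrics(y, yh)
    expect_gte(m$rmse, m$mae - 1e-12)
  }
  expect_error(regression_metrics(numeric(0), numeric(0)), "empty")
})

test_that("cross-validation partitions, stratifies and is deterministic", {
  st <- small_study()
  cv <- st$detect$cv
  expect_equal(sort(unique(cv$fold_id)), 1:10)
  expect_true(max(table(cv$fold_id)) - min(table(cv$fold_id)) <= 1)
  expect_true(all(cv$oof_scores >= 0 & cv$oof_scores <= 1))

  x <- feature_matrix(st$features[st$train, ])
  y <- st$labels[st$train]
  cv2 <- cross_validate(x, y, model_spec("detect", seed = 5), k = 10)
  expect_identical(cv$fold_metrics, cv2$fold_metrics)
  expect_identical(cv$oof_scores, cv2$oof_scores)

  few <- c(which(y)[1:8], which(!y)[1:8])  # both classes, each below k
  expect_error(cross_validate(x[few, ], y[few],
                              model_spec("detect", seed = 1), k = 10),
               "smaller k")
})

test_that("bootstrap protocol refits B times on a fixed test set", {
  st <- small_study()
  bt <- st$detect$bootstrap
  expect_equal(bt$n_repeats, 10L)
  expect_equal(nrow(bt$repeats), 10L)
  expect_equal(ncol(bt$test_scores), sum(st$test))  # test set never resampled
  with(bt$summary, {
    expect_true(all(lower <= mean + 1e-12))
    expect_true(all(mean <= upper + 1e-12))
  })
  x <- feature_matrix(st$features)
  bt2 <- bootstrap_test_evaluation(
    x[st$train, ], st$labels[st$train], x[st$test, ], st$labels[st$test],
    model_spec("detect", seed = 5), B = 10)
  expect_identical(bt$repeats, bt2$repeats)
})

test_that("degenerate bootstrap dispersion yields zero-width intervals", {
  # two repeats with identical metrics => SD 0 => CI width 0
  fake <- data.frame(repeat_id = 1:2, accuracy = c(80, 80))
  sdv <- sd(fake$accuracy)
  expect_equal(1.96 * sdv, 0)
})

test_that("calibration curve bins conserve counts and track event rates", {
  set.seed(5)
  scores <- runif(2000)
  labels <- rbinom(2000, 1, scores)
  cc <- calibration_curve(scores, labels, n_bins = 10)
  expect_equal(sum(cc$n), 2000)
  expect_lt(max(abs(cc$mean_score - cc$event_rate)), 0.05)

  all_pos <- calibration_curve(c(0.1, 0.6, 0.9), c(1, 1, 1), n_bins = 2)
  expect_true(all(all_pos$event_rate == 1))
  expect_error(calibration_curve(c(-0.1, 0.5), c(0, 1)), "\\[0, 1\\]")
})

test_that("MMSE severity bands reproduce the printed interval boundaries", {
  expect_identical(mmse_to_group(c(27, 26, 21, 20, 10, 9, 0, 30)),
                   c("CN", "MCI", "MCI", "moderate", "moderate", "severe",
                     "severe", "CN"))
  expect_error(mmse_to_group(31), "\\[0, 30\\]")
})

test_that("spec defaults pin the tuned forest hyperparameters", {
  det <- model_spec("detect")
  expect_equal(det$n_trees, 50L)
  expect_equal(det$max_depth, 16L)
  sev <- model_spec("severity")
  expect_equal(sev$min_samples_leaf, 2L)
  expect_error(fit_screening_model(matrix(rnorm(20), 10), rep(TRUE, 10),
                                   model_spec("detect")), "both classes")
})

test_that("prediction rejects feature-column mismatches", {
  st <- small_study()
  x <- feature_matrix(st$features)
  bad <- x[, c(2:ncol(x), 1)]
  expect_error(predict_screening(st$detect$model, bad), "training order")
})
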