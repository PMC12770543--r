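# brute-force Spearman via explicit mid-rank tables
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i])
      tied <- sum(v == v[i])
      r[i] <- less + (tied + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

test_that("tree attributions satisfy local accuracy on real model output", {
  st <- strong_study()
  att <- st$report$attributions
  expect_equal(att$prediction, unname(st$detect$test_scores),
               tolerance = 1e-6)
  gap <- abs(att$base_value + rowSums(att$contributions) - st$detect$test_scores)
  expect_lt(max(gap), 1e-6)
})

test_that("a single-feature stump credits all attribution to that feature", {
  set.seed(4)
  n <- 200
  # 'b' and 'c' are constant, so every depth-1 tree can only split on 'a'
  x <- cbind(a = rnorm(n), b = rep(1, n), c = rep(0, n))
  y <- x[, "a"] > 0
  m <- fit_screening_model(x, y, model_spec("detect", n_trees = 10L,
                                            max_depth = 1L, seed = 2))
  att <- feature_attributions(m, x)
  mass <- colSums(abs(att$contributions))
  expect_gt(mass[["a"]] / sum(mass), 0.999)
  expect_equal(att$prediction, unname(predict_screening(m, x)),
               tolerance = 1e-9)
})

test_that("a constant model attributes nothing", {
  set.seed(5)
  x <- cbind(a = rnorm(50), b = rnorm(50))
  y <- rep(5, 50)   # constant outcome: every node value equals 5
  m <- fit_screening_model(x, y, model_spec("severity", n_trees = 5L,
                                            seed = 3))
  att <- feature_attributions(m, x)
  expect_lt(max(abs(att$contributions)), 1e-9)
  expect_equal(att$base_value, 5)
  expect_equal(att$prediction, rep(5, 50))
})

test_that("permutation mode returns a global ranking", {
  st <- small_study()
  att <- feature_attributions(st$detect$model,
                              st$features[st$test, ], mode = "permutation",
                              seed = 9)
  expect_equal(att$mode, "permutation")
  expect_equal(nrow(att$ranking), 100L)
  expect_true(all(diff(att$ranking$mean_abs_contribution) <= 0))
})

test_that("attribution rejects feature mismatches", {
  st <- small_study()
  x <- feature_matrix(st$features[st$test, ])
  expect_error(feature_attributions(st$detect$model,
                                    x[, c(2:ncol(x), 1)]), "training order")
})

test_that("subgroup metrics partition the cohort and respect exchangeability", {
  labels <- rep(c(TRUE, FALSE), 20)
  scores <- rep(c(0.9, 0.1), 20)
  groups <- rep(c("g1", "g2"), each = 20)
  tab <- subgroup_performance(labels, scores, groups)
  expect_equal(sum(tab$n), 40)
  expect_equal(tab$sensitivity[1], tab$sensitivity[2])
  expect_equal(tab$roc_auc[1], tab$roc_auc[2])
  small <- subgroup_performance(labels, scores, c(rep("g1", 36), rep("g2", 4)))
  expect_true(small$flagged[small$group == "g2"])
  expect_error(subgroup_performance(labels, scores, rep(NA, 40)), "group")
})

test_that("demographic parity gap is the max pairwise rate difference", {
  expect_equal(demographic_parity_gap(c(1, 0, 1, 0), c("a", "a", "b", "b")), 0)
  expect_equal(demographic_parity_gap(
    c(rep(1, 2), rep(0, 8), rep(1, 6), rep(0, 4)),
    rep(c("a", "b"), each = 10)), 0.4)
  rates3 <- c(rep(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0), 1),   # 0.1
              rep(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 1),   # 0.3
              rep(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), 1))   # 0.4
  g3 <- rep(c("a", "b", "c"), each = 10)
  expect_equal(demographic_parity_gap(rates3, g3), 0.3)
  # symmetric under relabeling
  expect_equal(demographic_parity_gap(rates3, g3),
               demographic_parity_gap(rates3, rep(c("c", "a", "b"), each = 10)))
  expect_error(demographic_parity_gap(c(1, 0), c("a", "a")), "2 groups")
})

test_that("Spearman correlation matches a brute-force mid-rank oracle", {
  expect_equal(spearman_rank(1:10, (1:10)^2)$r, 1)
  expect_equal(spearman_rank(1:10, -(1:10)^3)$r, -1)
  r <- spearman_rank(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(r$r, oracle_spearman(c(1, 2, 2, 4), c(1, 3, 2, 4)),
               tolerance = 1e-12)
  set.seed(10)
  for (i in 1:40) {
    n <- sample(3:50, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- sample(1:8, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    mine <- spearman_rank(x, y)
    expect_equal(mine$r, oracle_spearman(x, y), tolerance = 1e-9)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-9)
  }
  expect_true(is.na(spearman_rank(rep(1, 5), 1:5)$r))
})

test_that("the probability-severity profile orders groups and correlates", {
  flat <- probability_severity_profile(rep(0.4, 6), c(29, 27, 25, 15, 9, 3))
  expect_true(all(flat$profile$mean == 0.4))
  st <- strong_study()
  pr <- st$report$profile
  expect_identical(pr$profile$group, c("severe", "moderate", "MCI", "CN"))
  expect_true(all(diff(pr$profile$mean) < 0))
  expect_lt(pr$spearman$r, 0)
  expect_error(probability_severity_profile(numeric(0), numeric(0)), "empty")
})

test_that("sex subgroup gaps are small under the sex-independent generator", {
  st <- strong_study()
  expect_lt(st$report$parity_sex, 0.15)
  expect_lt(st$report$odds_sex$sensitivity_gap, 0.15)
})
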