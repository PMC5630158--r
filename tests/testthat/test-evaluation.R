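test_that("regression metrics match their definitions", {
  y <- c(1, 2, 3, 5, 8)
  expect_equal(regression_metrics(y, y),
               list(r2 = 1, pearson = 1, spearman = 1))
  expect_equal(regression_metrics(y, rep(mean(y), 5))$r2, 0)
  expect_equal(regression_metrics(y, -y)$pearson, -1)
  expect_error(regression_metrics(rep(1, 5), y), "zero-variance")

  # r2 equals pearson^2 for least-squares-fitted predictions
  withr::local_seed(1)
  x <- rnorm(100)
  yy <- 2 * x + rnorm(100)
  pred <- fitted(lm(yy ~ x))
  m <- regression_metrics(yy, pred)
  expect_equal(m$r2, m$pearson^2, tolerance = 1e-12)
})

test_that("AUCs agree with exhaustive pairwise and step oracles", {
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(classification_metrics(lab, c(4, 3, 2, 1)),
               list(auc_roc = 1, auc_pr = 1))
  expect_error(classification_metrics(rep(TRUE, 4), 1:4), "both classes")

  withr::local_seed(2)
  for (rep in 1:12) {
    n <- sample(10:50, 1)
    labels <- runif(n) < 0.3
    if (!any(labels) || all(labels)) next
    scores <- sample(round(rnorm(n), 1), n, replace = TRUE) # force ties
    got <- classification_metrics(labels, scores)
    expect_equal(got$auc_roc, auc_pairwise_ref(labels, scores),
                 tolerance = 1e-12)
    expect_equal(got$auc_pr, auc_pr_ref(labels, scores), tolerance = 1e-12)
  }
})

test_that("random scores land at AUC-ROC 1/2 and AUC-PR at prevalence", {
  withr::local_seed(3)
  labels <- seq_len(500) <= 55 # 11% positives
  roc <- pr <- numeric(200)
  for (b in 1:200) {
    s <- runif(500)
    m <- classification_metrics(labels, s)
    roc[b] <- m$auc_roc
    pr[b] <- m$auc_pr
  }
  expect_lt(abs(mean(roc) - 0.5), 0.01)
  expect_lt(abs(mean(pr) - 0.11), 0.02)
})

test_that("pooled metrics equal recomputation from concatenated folds", {
  withr::local_seed(4)
  lib <- generate_library(synthetic_config(n = 200, length = 50, seed = 31))
  cv <- suppressWarnings(double_loop_cv(
    lib$records, featurization_config(k_max = 2, include_positional = FALSE),
    hyperparameter_grid(m = 10, r = 0.1, f = 0.8),
    n_folds = 3, n_inner = 2, n_trees = 50, fdr = 0.999, seed = 8))
  pm <- pooled_test_metrics(cv)
  idx <- unlist(lapply(cv$folds, `[[`, "test_idx"))
  pred <- unlist(lapply(cv$folds, `[[`, "predictions"))
  direct <- regression_metrics(lib$records$activity[idx], pred)
  expect_equal(pm$pooled$r2, direct$r2)
  expect_equal(pm$pooled$spearman, direct$spearman)
  # fold-order invariance
  cv_rev <- cv
  cv_rev$folds <- rev(cv$folds)
  expect_equal(pooled_test_metrics(cv_rev)$pooled$r2, pm$pooled$r2)
  # single fold pools to itself
  cv1 <- cv
  cv1$folds <- cv$folds[1]
  expect_equal(pooled_test_metrics(cv1)$pooled$r2, cv$folds[[1]]$metrics$r2)
})

test_that("group-division permutation test separates signal from chance", {
  withr::local_seed(5)
  n <- 240
  groups <- rep(c("dsrna", "retro", "human_5utr"), each = n / 3)
  u <- runif(n)
  y <- ifelse(groups == "dsrna", 2 * u, 0) + rnorm(n, 1, 0.6)
  lib <- tiny_library(replicate(n, random_rna(30)), y)
  lib$group <- groups
  lib$covariate <- u
  # cheap injected fit: R^2 of a linear fit on the planted covariate
  fit_fn <- function(recs, seed) summary(lm(activity ~ covariate,
                                            data = recs))$r.squared
  observed <- vapply(split(lib, lib$group),
                     function(g) fit_fn(g, 1), numeric(1))
  gt <- group_division_test(lib, observed, n_perm = 99, seed = 9,
                            fit_fn = fit_fn)
  expect_lt(gt$p, 0.05)
  expect_gte(gt$p, 1 / 100) # add-one lower bound
  # a division unrelated to activity is not called significant
  y0 <- rnorm(n, 1, 0.6)
  lib0 <- lib
  lib0$activity <- y0
  obs0 <- vapply(split(lib0, lib0$group),
                 function(g) fit_fn(g, 1), numeric(1))
  gt0 <- group_division_test(lib0, obs0, n_perm = 99, seed = 10,
                             fit_fn = fit_fn)
  expect_gt(gt0$p, 0.05)
})

test_that("incidence subsampling recovers the positives/performance trend", {
  withr::local_seed(6)
  n <- 300
  u <- rpois(n, 2)
  y <- u + rnorm(n, 0, 0.8)
  lib <- tiny_library(replicate(n, random_rna(30)), y,
                      threshold = quantile(y, 0.7))
  lib$covariate <- u
  fit_fn <- function(recs, seed) {
    # correlation-based skill shrinks as informative positives are removed
    summary(lm(activity ~ covariate, data = recs))$r.squared
  }
  curve <- incidence_subsample_curve(lib, targets = c(10, 40, sum(lib$active)),
                                     n_reps = 5, seed = 11, fit_fn = fit_fn)
  expect_equal(nrow(curve), 3)
  expect_true(all(diff(curve$mean_r2) > -0.05)) # non-decreasing trend
  # full positive count reproduces the full-data fit exactly
  expect_equal(curve$mean_r2[3], fit_fn(lib, 1))
  expect_equal(curve$sd_r2[3], 0)
})
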