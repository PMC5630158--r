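test_that("importance normalization and aggregation", {
  f1 <- mock_fold(NULL, c("a", "b", "c"), 1:5,
                  importance = c(a = 2, b = 4, c = 1))
  expect_equal(fold_importances(f1), c(a = 0.5, b = 1.0, c = 0.25))
  expect_equal(names(which.max(fold_importances(f1))),
               names(which.max(f1$importance)))
  expect_warning(z <- fold_importances(
    mock_fold(NULL, "a", 1:5, importance = c(a = 0))), "zero")
  expect_equal(z, c(a = 0))

  # aggregation over folds with partial selection
  f2 <- mock_fold(NULL, c("a", "b"), 1:5, importance = c(a = 1, b = 5))
  prof <- aggregate_importances(list(f1, f2))
  expect_equal(prof$folds_selected[prof$feature == "c"], 1)
  expect_equal(prof$folds_selected[prof$feature == "a"], 2)
  expect_equal(prof$mean_norm_importance[prof$feature == "a"],
               mean(c(0.5, 0.2)))
  expect_error(aggregate_importances(list()), "no fold")
})

test_that("partial dependence equals the brute-force substitution oracle", {
  withr::local_seed(1)
  n <- 20
  V <- cbind(x = rbinom(n, 3, 0.4), z = rpois(n, 1))
  colnames(V) <- c("x|global", "z|global")
  stump <- function(X) ifelse(X[, "x|global"] <= 0.5, 0, 1)
  fold <- mock_fold(stump, colnames(V), train_idx = 1:12)
  cv <- mock_cv(V, list(fold))

  pd <- partial_dependence(cv, "x|global")
  # oracle: substitute each value into the training rows and average
  oracle <- vapply(sort(unique(V[, 1])), function(v) {
    Xs <- V[1:12, , drop = FALSE]
    Xs[, 1] <- v
    mean(stump(Xs))
  }, numeric(1))
  expect_equal(pd$ybar, oracle)
  expect_equal(pd$ybar[pd$values == 0], 0)
  expect_equal(pd$ybar[pd$values == 1], 1)
  expect_equal(classify_direction(pd), "positive")

  # a constant model has a flat curve
  fold_c <- mock_fold(function(X) rep(3.3, nrow(X)), colnames(V), 1:12)
  pd_c <- partial_dependence(mock_cv(V, list(fold_c)), "z|global")
  expect_true(all(pd_c$ybar == 3.3))

  # curves are averaged across folds
  fold2 <- mock_fold(function(X) rep(1, nrow(X)), colnames(V), 13:20)
  pd_m <- partial_dependence(mock_cv(V, list(fold, fold2)), "x|global")
  expect_equal(pd_m$ybar, (oracle + 1) / 2)
})

test_that("directionality follows the average-derivative rule", {
  expect_equal(classify_direction(list(values = 0:2, ybar = c(0, 1, 2))),
               "positive")
  expect_equal(classify_direction(list(values = 0:2, ybar = c(2, 1, 0))),
               "negative")
  expect_equal(classify_direction(list(values = 0:1, ybar = c(1, 1))),
               "negative") # flat falls to the negative class
  expect_equal(classify_direction(list(values = 0, ybar = 5)), "negative")
  # cancellation is judged by the mean slope
  expect_equal(classify_direction(list(values = c(0, 1, 3),
                                       ybar = c(0, 1, 0.5))), "positive")
})

test_that("robust/predictive selection applies both criteria", {
  prof <- data.frame(
    feature = c("u", "v", "w"),
    folds_selected = c(10, 9, 10),
    mean_norm_importance = c(0.15, 0.9, 0.05))
  dirs <- c(u = "positive", v = "negative", w = "negative")
  got <- select_robust_predictive(prof, n_folds = 10, directions = dirs)
  expect_equal(got$feature, "u")       # v lacks a fold, w lacks importance
  expect_equal(got$signed_effect, 0.15)
})

test_that("common/unique split is a disjoint cover of selected features", {
  eff <- function(names) data.frame(name = names)
  res <- common_and_unique(list(dsrna = eff(c("a", "b")),
                                retro = eff(c("b", "c")),
                                human_5utr = eff("c")))
  expect_setequal(res$common$feature, c("b", "c"))
  expect_equal(res$unique$feature, "a")
  expect_length(intersect(res$common$feature, res$unique$feature), 0)
  expect_setequal(c(res$common$feature, res$unique$feature), c("a", "b", "c"))
})

test_that("islands are maximal runs of adjacent robust windows", {
  we <- data.frame(window_start = c(-60, -50, -40),
                   signed_effect = c(0.3, 0.4, 0.2))
  isl <- find_islands(we)
  expect_equal(nrow(isl), 1)
  expect_equal(c(isl$start, isl$end), c(-60, -20))
  expect_equal(isl$n_windows, 3)

  expect_equal(nrow(find_islands(
    data.frame(window_start = c(-60, -30), signed_effect = c(1, 1)))), 0)

  two <- find_islands(data.frame(
    window_start = c(-150, -140, -60, -50, -40),
    signed_effect = c(-0.2, -0.3, 0.5, 0.6, 0.4)))
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(-150, -60))
})

test_that("consensus requires two sign-agreeing groups and takes the max", {
  gw <- data.frame(group = c("dsrna", "retro"),
                   window_start = -50, signed_effect = c(0.3, 0.2))
  out <- consensus_effects(gw)
  expect_equal(out$consensus, 0.3)
  expect_equal(out$supporting_groups, "dsrna,retro")

  gw2 <- data.frame(group = c("dsrna", "retro"),
                    window_start = -50, signed_effect = c(0.3, -0.2))
  expect_true(is.na(consensus_effects(gw2)$consensus))

  gw3 <- data.frame(group = "dsrna", window_start = -50, signed_effect = 0.3)
  expect_true(is.na(consensus_effects(gw3)$consensus))
})

test_that("GC content comparison uses the rank-sum test", {
  out <- gc_content_compare(c("GCGC", "GGCC"), c("AUAU", "AAUU"))
  expect_equal(out$gc_a, c(1, 1))
  expect_equal(out$gc_b, c(0, 0))
  withr::local_seed(2)
  a <- replicate(10, random_rna(100, gc = 0.8))
  b <- replicate(10, random_rna(100, gc = 0.2))
  expect_lt(gc_content_compare(a, b)$p, 1e-3) # disjoint GC ranges
  expect_gt(gc_content_compare(a, a)$p, 0.9)  # identical groups
})
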