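test_that("count-feature association matches cor.test on tied data", {
  withr::local_seed(1)
  for (rep in 1:5) {
    x <- rpois(50, 0.8)
    y <- rnorm(50) + 0.2 * x
    y[sample(50, 20)] <- 1.0 # heavy ties, as under activity censoring
    a <- associate(x, y, "count")
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(a$statistic, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(a$p, ct$p.value, tolerance = 1e-12)
  }
  # monotone extremes
  y <- rnorm(20)
  expect_equal(associate(rank(y), y, "count")$statistic, 1)
  expect_equal(associate(rev(rank(y)), rev(y), "count")$statistic, 1)
  expect_equal(associate(max(rank(y)) - rank(y), y, "count")$statistic, -1)
})

test_that("presence-feature association matches wilcox.test", {
  withr::local_seed(2)
  for (rep in 1:5) {
    x <- as.numeric(runif(40) < 0.4)
    y <- round(rnorm(40) + x, 1)
    a <- associate(x, y, "presence")
    wt <- suppressWarnings(
      wilcox.test(y[x == 1], y[x == 0], exact = FALSE, correct = TRUE))
    expect_equal(a$statistic, unname(wt$statistic))
    expect_equal(a$p, wt$p.value, tolerance = 1e-12)
  }
  # identical distributions in both groups give a large p
  y <- rep(c(5, 7), 10)
  x <- rep(c(0, 1), each = 10)
  expect_gt(associate(x, y, "presence")$p, 0.5)
})

test_that("degenerate features are flagged, not significant", {
  y <- rnorm(10)
  a <- associate(rep(0, 10), y, "count")
  expect_true(is.na(a$statistic))
  expect_equal(a$p, 1)
  expect_equal(a$prevalence, 0)
  a2 <- associate(rep(1, 10), y, "presence")
  expect_equal(a2$p, 1)
})

test_that("BH matches the brute-force step-up reference", {
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(bh$rejected)) # i/m * q thresholds: .0125,.025,.0375,.05
  expect_false(any(benjamini_hochberg(c(0.5, 0.6), 0.05)$rejected))
  b0 <- benjamini_hochberg(rep(0, 5), 0.05)
  expect_true(all(b0$rejected) && all(b0$q == 0))
  expect_length(benjamini_hochberg(numeric(0), 0.05)$q, 0)

  withr::local_seed(3)
  for (rep in 1:10) {
    ps <- runif(sample(5:200, 1))^sample(1:3, 1)
    ref <- bh_stepup_ref(ps, 0.05)
    got <- benjamini_hochberg(ps, 0.05)
    expect_equal(got$q, ref$q, tolerance = 1e-12)
    expect_identical(got$rejected, ref$rejected)
  }
})

test_that("pre-selection enforces both FDR and prevalence", {
  withr::local_seed(4)
  lib <- generate_library(synthetic_config(n = 300, seed = 9))
  fm <- build_matrix(lib$records, featurization_config(
    k_max = 2, include_positional = FALSE))
  y <- lib$records$activity

  # a feature identical to activity at full prevalence must survive;
  # the same signal at 5% prevalence must not
  vals <- cbind(fm$values, Matrix::Matrix(rank(y), ncol = 1, sparse = TRUE))
  rare <- as.numeric(rank(y) > length(y) - 15) # marks the top-15 activities
  vals <- cbind(vals, Matrix::Matrix(rare, ncol = 1, sparse = TRUE))
  colnames(vals) <- c(colnames(fm$values), "oracle|global", "rare|global")
  fm2 <- fm
  fm2$values <- vals
  fm2$descriptors <- rbind(
    fm$descriptors,
    data.frame(name = c("oracle|global", "rare|global"),
               kmer = c("oracle", "rare"), scope = "global",
               window_start = NA, window_end = NA, representation = "count"))
  sel <- preselect(fm2, y)
  res <- sel$results
  expect_true(res$kept[res$name == "oracle|global"])
  expect_false(res$kept[res$name == "rare|global"])
  expect_lt(res$prevalence[res$name == "rare|global"], 0.10)
  expect_lt(res$q[res$name == "rare|global"], 0.05) # removed by prevalence alone
  # column order preserved in the reduced matrix
  expect_identical(colnames(sel$matrix$values), res$name[res$kept])

  # type-I control: permuted activity keeps essentially nothing
  yp <- sample(y)
  selp <- suppressWarnings(preselect(fm, yp))
  expect_lte(sum(selp$results$kept), ceiling(0.01 * ncol(fm$values)))
})

test_that("pre-selection keeps a planted monotone association", {
  withr::local_seed(5)
  n <- 400
  noise <- matrix(rpois(n * 50, 1), n)
  signal <- rpois(n, 2)
  y <- signal + rnorm(n, 0, 0.5)
  vals <- Matrix::Matrix(cbind(signal, noise), sparse = TRUE)
  colnames(vals) <- paste0("f", 0:50, "|global")
  fm <- structure(list(
    values = vals,
    descriptors = data.frame(name = colnames(vals), kmer = "x",
                             scope = "global", window_start = NA,
                             window_end = NA, representation = "count"),
    sample_ids = as.character(seq_len(n)),
    config = featurization_config()), class = "ires_feature_matrix")
  sel <- preselect(fm, y)
  expect_true(sel$results$kept[1])
  # and an all-noise screen keeps about nothing at FDR 0.05
  expect_lte(sum(sel$results$kept[-1]), 3)
})
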