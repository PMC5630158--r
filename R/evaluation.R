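#' Regression performance metrics
#'
#' `r2` is computed as `1 - SS_res / SS_tot` on the given pairs (it can be
#' negative for predictors worse than the mean); `pearson` and `spearman`
#' are the standard correlation coefficients.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return list with `r2`, `pearson`, `spearman`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("zero-variance y_true: R^2 undefined")
  list(r2 = 1 - sum((y_true - y_pred)^2) / ss_tot,
       pearson = suppressWarnings(stats::cor(y_true, y_pred)),
       spearman = suppressWarnings(stats::cor(y_true, y_pred,
                                              method = "spearman")))
}

#' Classification performance metrics for activity calls
#'
#' AUC-ROC uses the rank (Mann-Whitney) formulation with ties mid-ranked.
#' AUC-PR integrates the precision-recall curve as a step function over
#' distinct score thresholds in decreasing order (no optimistic linear
#' interpolation); tied scores enter as one block.
#'
#' @param labels logical vector (TRUE = positive/active).
#' @param scores numeric prediction scores.
#' @return list with `auc_roc`, `auc_pr`.
#' @export
classification_metrics <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc_roc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # positions of the last element of each tied-score block, in order
  cut <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[cut]
  fp <- cumsum(!l)[cut]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  auc_pr <- sum(diff(c(0, recall)) * precision)
  list(auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Full metric set for one prediction vector
#'
#' @param y_true,y_pred numeric activity and predictions.
#' @param active logical activity calls; when both classes are present the
#'   classification metrics are added, otherwise they are `NA`.
#' @return a `metric_set` list: `r2`, `pearson`, `spearman`, `auc_roc`,
#'   `auc_pr`, `n`, `n_positive`.
#' @export
metric_set <- function(y_true, y_pred, active) {
  m <- regression_metrics(y_true, y_pred)
  cls <- if (sum(active) > 0 && sum(!active) > 0)
    classification_metrics(active, y_pred)
  else list(auc_roc = NA_real_, auc_pr = NA_real_)
  structure(c(m, cls, list(n = length(y_true), n_positive = sum(active))),
            class = "metric_set")
}

#' Pooled and per-fold test metrics of a cross-validated model
#'
#' Headline metrics are computed on the predictions pooled across all outer
#' test folds (the folds partition the data, so pooling is order-invariant);
#' per-fold metrics with mean and sd are reported alongside.
#'
#' @param cv an `ires_cv_result` (or list of fold models plus `records`).
#' @return list with `pooled` (a [metric_set()]), `per_fold` (data.frame)
#'   and `summary` (mean/sd per metric across folds).
#' @export
pooled_test_metrics <- function(cv) {
  folds <- cv$folds
  y <- cv$records$activity
  act <- cv$records$active
  idx <- unlist(lapply(folds, `[[`, "test_idx"))
  pred <- unlist(lapply(folds, `[[`, "predictions"))
  stopifnot(!anyDuplicated(idx))
  pooled <- metric_set(y[idx], pred, act[idx])
  per_fold <- do.call(rbind, lapply(folds, function(f)
    data.frame(fold = f$fold, r2 = f$metrics$r2, pearson = f$metrics$pearson,
               spearman = f$metrics$spearman, auc_roc = f$metrics$auc_roc,
               auc_pr = f$metrics$auc_pr, n = f$metrics$n,
               n_positive = f$metrics$n_positive)))
  met <- c("r2", "pearson", "spearman", "auc_roc", "auc_pr")
  summary <- data.frame(
    metric = met,
    mean = vapply(per_fold[met], mean, numeric(1), na.rm = TRUE),
    sd = vapply(per_fold[met], stats::sd, numeric(1), na.rm = TRUE),
    row.names = NULL)
  list(pooled = pooled, per_fold = per_fold, summary = summary)
}

# Default per-group fit: a deliberately scaled-down double-loop CV pipeline
# (k <= 2, global features, one grid cell, 3x3 CV, 100 trees) returning the
# pooled test R^2 for one set of records.
default_group_fit <- function(records, seed = 1) {
  cv <- double_loop_cv(
    records, featurization_config(k_max = 2, include_positional = FALSE),
    grid = hyperparameter_grid(m = 15, r = 0.1, f = 0.8),
    n_folds = 3, n_inner = 3, n_trees = 100, seed = seed)
  pooled_test_metrics(cv)$pooled$r2
}

#' Permutation support for the group division
#'
#' Tests whether the observed variation in predictive power across origin
#' groups could arise for a random division of the same sizes: group labels
#' are permuted (preserving group sizes), the per-group pipeline is re-run
#' on each permuted division, and the dispersion of per-group R^2 values is
#' compared with the observed one.  The p-value uses the add-one estimator
#' `(1 + #{perm >= observed}) / (n_perm + 1)`.
#'
#' @param records an `ires_library` with >= 2 groups.
#' @param observed_r2 named numeric of observed per-group R^2.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param fit_fn function(records, seed) -> R^2 used to score one group;
#'   defaults to a scaled-down double-loop CV pipeline.
#' @param statistic dispersion statistic across groups: `"variance"`
#'   (default) or `"range"` (max - min).
#' @return list with `p`, `observed` (statistic), `permuted` (vector).
#' @export
group_division_test <- function(records, observed_r2, n_perm = 100, seed = 1,
                                fit_fn = default_group_fit,
                                statistic = c("variance", "range")) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1, length(observed_r2) >= 2)
  stat_fn <- if (statistic == "variance") stats::var
  else function(x) max(x) - min(x)
  groups <- names(observed_r2)
  obs <- stat_fn(unname(observed_r2))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      shuffled <- records
      shuffled$group <- sample(records$group)
      r2 <- vapply(groups, function(g) {
        sub <- shuffled[shuffled$group == g, , drop = FALSE]
        attr(sub, "threshold") <- attr(records, "threshold")
        fit_fn(sub, derive_seed(seed, b))
      }, numeric(1))
      stat_fn(r2)
    }, numeric(1))
  })
  list(p = (1 + sum(perm >= obs)) / (n_perm + 1), observed = obs,
       permuted = perm)
}

#' Predictive power as a function of positive-sequence incidence
#'
#' Downsamples the active sequences of one group to each target count
#' (keeping all inactive sequences), re-runs the fit, and reports the mean
#' and sd of test R^2 across repetitions.
#'
#' @param records an `ires_library` (one group).
#' @param targets integer vector of positive counts to downsample to; each
#'   must not exceed the available positives.
#' @param n_reps random subsamples per target (default 5).
#' @param seed RNG seed.
#' @param fit_fn function(records, seed) -> R^2 (default: scaled pipeline).
#' @return data.frame with `target`, `mean_r2`, `sd_r2`.
#' @export
incidence_subsample_curve <- function(records, targets, n_reps = 5, seed = 1,
                                      fit_fn = default_group_fit) {
  pos <- which(records$active)
  neg <- which(!records$active)
  stopifnot(all(targets <= length(pos)), all(targets >= 1))
  rows <- with_seed(seed, {
    lapply(targets, function(tg) {
      r2 <- vapply(seq_len(n_reps), function(b) {
        keep <- sort(c(sample(pos, tg), neg))
        sub <- records[keep, , drop = FALSE]
        attr(sub, "threshold") <- attr(records, "threshold")
        fit_fn(sub, derive_seed(seed, tg * 100 + b))
      }, numeric(1))
      data.frame(target = tg, mean_r2 = mean(r2), sd_r2 = stats::sd(r2))
    })
  })
  do.call(rbind, rows)
}
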