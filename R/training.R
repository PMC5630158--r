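#' Boosting hyperparameters
#'
#' Settings of the stochastic gradient-boosted regression tree ensemble:
#' `n_trees` least-squares trees, each fit to the gradient of the residual
#' error on a random fraction `f` of the training samples with learning
#' rate `r`; trees have unbounded depth with complexity controlled by the
#' minimum number of training samples per leaf `m`; every split considers
#' `floor(sqrt(M'))` randomly drawn features out of the M' pre-selected
#' ones (redrawn per node by default, per tree optionally).
#'
#' @param n_trees number of boosted trees (default 1000).
#' @param m minimum training samples per leaf.
#' @param r learning rate (> 0).
#' @param f subsample fraction per tree, in (0, 1].
#' @param feature_draw `"node"` or `"tree"`: where the sqrt(M') feature
#'   subset is redrawn.
#' @return a `hyperparameters` list.
#' @export
hyperparameters <- function(n_trees = 1000, m = 15, r = 0.1, f = 0.8,
                            feature_draw = c("node", "tree")) {
  feature_draw <- match.arg(feature_draw)
  stopifnot(n_trees >= 1, m >= 1, r > 0, f > 0, f <= 1)
  structure(list(n_trees = as.integer(n_trees), m = as.integer(m), r = r,
                 f = f, feature_draw = feature_draw),
            class = "hyperparameters")
}

#' Hyperparameter grid for the double-loop CV
#'
#' Cartesian product of candidate values for (m, r, f), enumerated
#' deterministically (f slowest, then r, then m).
#'
#' @param m,r,f candidate values for the leaf-size, learning-rate and
#'   subsampling parameters.
#' @return data.frame with one row per grid cell.
#' @export
hyperparameter_grid <- function(m = c(15, 30, 60), r = c(0.01, 0.05, 0.1),
                                f = c(0.5, 0.8)) {
  stopifnot(length(m) > 0, length(r) > 0, length(f) > 0)
  g <- expand.grid(m = m, r = r, f = f, KEEP.OUT.ATTRS = FALSE)
  g$cell <- seq_len(nrow(g))
  g
}

#' Activity-stratified cross-validation folds
#'
#' Randomly partitions samples into folds such that the numbers of active
#' (above detection floor) and inactive sequences are each split as evenly
#' as possible (counts differ by at most 1 per stratum).
#'
#' @param active logical vector of activity calls, or an `ires_library`
#'   (its `active` column is used).
#' @param n_folds number of folds.
#' @param seed RNG seed; the same seed yields the same plan.
#' @return an `ires_cv_plan`: list with `fold` (fold id per sample),
#'   `n_folds`, `seed`.
#' @export
stratified_folds <- function(active, n_folds = 10, seed = 1) {
  if (is.data.frame(active)) active <- active$active
  stopifnot(is.logical(active), n_folds >= 2, length(active) >= n_folds)
  if (sum(active) < n_folds)
    warning("fewer active samples than folds; some folds get none")
  fold <- integer(length(active))
  with_seed(seed, {
    for (stratum in c(TRUE, FALSE)) {
      idx <- which(active == stratum)
      if (length(idx) == 0) next
      fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  structure(list(fold = fold, n_folds = as.integer(n_folds), seed = seed),
            class = "ires_cv_plan")
}

#' Train a stochastic gradient-boosted tree ensemble
#'
#' Least-squares boosting per the contract in [hyperparameters()], backed
#' by xgboost (histogram trees, loss-guided growth with unbounded depth).
#' Training is deterministic given `seed` and single-threaded.
#'
#' @param X numeric matrix or sparse Matrix of features (columns named).
#' @param activity numeric response.
#' @param hp a [hyperparameters()] object.
#' @param seed RNG seed for subsampling and feature draws.
#' @return an `ires_ensemble` with elements `booster`, `feature_names`,
#'   `hp`, `seed`.
#' @export
train_ensemble <- function(X, activity, hp = hyperparameters(), seed = 1) {
  if (inherits(X, "ires_feature_matrix")) X <- X$values
  Mp <- ncol(X)
  if (Mp < 1) stop("refusing to train on an empty feature matrix")
  if (is.null(colnames(X))) stop("feature columns must be named")
  stopifnot(nrow(X) == length(activity))
  colsample <- max(1, floor(sqrt(Mp))) / Mp
  pars <- list(objective = "reg:squarederror", eta = hp$r,
               subsample = hp$f, min_child_weight = hp$m,
               tree_method = "hist", grow_policy = "lossguide",
               max_depth = 0, nthread = 1, seed = as.integer(seed))
  if (hp$feature_draw == "node") pars$colsample_bynode <- colsample
  else pars$colsample_bytree <- colsample
  # densify: zero counts are observed values, not missing data (sparse
  # zeros would be routed down xgboost's default split direction)
  booster <- with_seed(seed, {
    d <- xgboost::xgb.DMatrix(as.matrix(X), label = activity, nthread = 1)
    xgboost::xgb.train(params = pars, data = d, nrounds = hp$n_trees,
                       verbose = 0)
  })
  structure(list(booster = booster, feature_names = colnames(X), hp = hp,
                 seed = seed),
            class = "ires_ensemble")
}

#' Predict IRES activity with a trained ensemble
#'
#' @param object an `ires_ensemble`.
#' @param newdata feature matrix (or `ires_feature_matrix`) containing at
#'   least the training features; columns are aligned by name.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.ires_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "ires_feature_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  unname(predict(object$booster, newdata))
}

# Raw per-feature importance (total split-gain share, summing to 1 over the
# model); features never used for a split get 0.
raw_importance <- function(ensemble) {
  imp <- stats::setNames(numeric(length(ensemble$feature_names)),
                         ensemble$feature_names)
  tab <- tryCatch(xgboost::xgb.importance(model = ensemble$booster),
                  error = function(e) NULL)
  if (!is.null(tab) && nrow(tab) > 0) imp[tab$Feature] <- tab$Gain
  imp
}

# Internal generic predictor: fold ensembles are `ires_ensemble`s in the
# pipeline, but tests may supply a plain function X -> predictions or any
# object with a predict() method.
predict_model <- function(model, X) {
  if (is.function(model)) model(X)
  else as.numeric(predict(model, X))
}

#' Double-loop cross-validated training
#'
#' For every outer fold, the outer training set is itself split into
#' `n_inner` stratified folds; every hyperparameter cell (m, r, f) is
#' trained on each inner training set (with feature pre-selection
#' recomputed there) and scored by R^2 on the inner validation set.  The
#' cell with the highest mean inner R^2 (ties: smaller r, then larger m,
#' then declaration order) is used to train the final fold model on the
#' full outer training set, with pre-selection recomputed there, and is
#' evaluated on the held-out outer fold.  Held-out data never enter
#' pre-selection or fitting for their fold.
#'
#' @param records an `ires_library`.
#' @param cfg a [featurization_config()].
#' @param grid a [hyperparameter_grid()].
#' @param plan an [stratified_folds()] plan for the outer loop, or `NULL`
#'   to create one from `seed`.
#' @param n_folds,n_inner outer/inner fold counts (used when `plan` is
#'   `NULL`).
#' @param n_trees trees per ensemble.
#' @param fdr,min_prevalence pre-selection settings (see [preselect()]).
#' @param seed master seed; fold and model seeds are derived from it.
#' @param verbose print per-fold progress.
#' @return an `ires_cv_result`: list with `folds` (one fold model per outer
#'   fold: chosen `hp`, kept `features`, `ensemble`, `train_idx`,
#'   `test_idx`, `predictions`, `metrics`, `importance`,
#'   `norm_importance`), the outer `plan`, the full feature `matrix`,
#'   `records` and the `grid`.
#' @export
double_loop_cv <- function(records, cfg = featurization_config(),
                           grid = hyperparameter_grid(), plan = NULL,
                           n_folds = 10, n_inner = 10, n_trees = 1000,
                           fdr = 0.05, min_prevalence = 0.10, seed = 1,
                           verbose = FALSE) {
  fm <- build_matrix(records, cfg)
  y <- records$activity
  if (is.null(plan))
    plan <- stratified_folds(records$active, n_folds, derive_seed(seed, 1))
  n_folds <- plan$n_folds

  folds <- vector("list", n_folds)
  for (ko in seq_len(n_folds)) {
    test_idx <- which(plan$fold == ko)
    train_idx <- which(plan$fold != ko)
    inner <- stratified_folds(records$active[train_idx], n_inner,
                              derive_seed(seed, 100 + ko))
    scores <- matrix(NA_real_, nrow(grid), n_inner)
    for (ki in seq_len(n_inner)) {
      it <- train_idx[inner$fold != ki]
      iv <- train_idx[inner$fold == ki]
      sel <- suppressWarnings(
        preselect(subset_rows(fm, it), y[it], fdr, min_prevalence))
      if (ncol(sel$matrix$values) == 0) {
        scores[, ki] <- -Inf
        next
      }
      Xi <- sel$matrix$values
      Xv <- fm$values[iv, colnames(Xi), drop = FALSE]
      for (g in seq_len(nrow(grid))) {
        hp <- hyperparameters(n_trees, grid$m[g], grid$r[g], grid$f[g])
        scores[g, ki] <- tryCatch({
          ens <- train_ensemble(Xi, y[it], hp,
                                derive_seed(seed, 1e4 + ko * 1000 + ki * 50 + g))
          regression_metrics(y[iv], predict(ens, Xv))$r2
        }, error = function(e) {
          warning(sprintf("grid cell %d failed in fold %d.%d: %s",
                          g, ko, ki, conditionMessage(e)))
          -Inf
        })
      }
    }
    mean_score <- rowMeans(scores)
    ord <- order(-mean_score, grid$r, -grid$m, grid$cell)
    best <- ord[1]
    hp <- hyperparameters(n_trees, grid$m[best], grid$r[best], grid$f[best])

    sel <- preselect(subset_rows(fm, train_idx), y[train_idx], fdr,
                     min_prevalence)
    if (ncol(sel$matrix$values) == 0)
      stop("no feature survived pre-selection on outer fold ", ko)
    ens <- train_ensemble(sel$matrix$values, y[train_idx], hp,
                          derive_seed(seed, 500 + ko))
    Xt <- fm$values[test_idx, ens$feature_names, drop = FALSE]
    pred <- predict(ens, Xt)
    imp <- raw_importance(ens)
    folds[[ko]] <- structure(list(
      fold = ko, hp = hp, features = ens$feature_names, ensemble = ens,
      train_idx = train_idx, test_idx = test_idx, predictions = pred,
      metrics = metric_set(y[test_idx], pred, records$active[test_idx]),
      importance = imp,
      norm_importance = normalize_importance(imp),
      inner_mean_r2 = mean_score), class = "ires_fold_model")
    if (verbose)
      message(sprintf("fold %d: m=%d r=%g f=%g, %d features, test R2 = %.3f",
                      ko, hp$m, hp$r, hp$f, length(ens$feature_names),
                      folds[[ko]]$metrics$r2))
  }
  structure(list(folds = folds, plan = plan, matrix = fm, records = records,
                 grid = grid, seed = seed),
            class = "ires_cv_result")
}

#' @export
print.ires_cv_result <- function(x, ...) {
  r2 <- vapply(x$folds, function(f) f$metrics$r2, numeric(1))
  cat(sprintf("ires_cv_result: %d outer folds, %d samples, mean test R2 = %.3f\n",
              length(x$folds), nrow(x$matrix$values), mean(r2)))
  invisible(x)
}
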