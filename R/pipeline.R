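#' End-to-end IRES activity analysis for one set of sequences
#'
#' Convenience wrapper chaining featurization, the double-loop
#' cross-validated training and the interpretation layer: returns the
#' cross-validation result, the pooled/per-fold test metrics and the
#' robust/predictive signed feature effects.
#'
#' @param records an `ires_library`.
#' @param cfg a [featurization_config()].
#' @param grid a [hyperparameter_grid()].
#' @param n_folds,n_inner outer/inner CV fold counts.
#' @param n_trees trees per ensemble.
#' @param fdr,min_prevalence pre-selection settings.
#' @param effect_threshold minimum mean normalized importance for the
#'   effects table.
#' @param seed master seed.
#' @return an `ires_analysis` list: `cv`, `metrics`, `effects`.
#' @export
run_ires_pipeline <- function(records, cfg = featurization_config(),
                              grid = hyperparameter_grid(),
                              n_folds = 10, n_inner = 10, n_trees = 1000,
                              fdr = 0.05, min_prevalence = 0.10,
                              effect_threshold = 0.1, seed = 1) {
  cv <- double_loop_cv(records, cfg, grid, n_folds = n_folds,
                       n_inner = n_inner, n_trees = n_trees, fdr = fdr,
                       min_prevalence = min_prevalence, seed = seed)
  structure(list(cv = cv, metrics = pooled_test_metrics(cv),
                 effects = feature_effects(cv, effect_threshold)),
            class = "ires_analysis")
}

#' @export
print.ires_analysis <- function(x, ...) {
  p <- x$metrics$pooled
  cat(sprintf(
    "ires_analysis: n = %d (%d active)\npooled test: R2 = %.3f, r = %.3f, rho = %.3f, AUC-ROC = %.3f, AUC-PR = %.3f\n",
    p$n, p$n_positive, p$r2, p$pearson, p$spearman, p$auc_roc, p$auc_pr))
  cat(sprintf("%d robust & predictive feature(s)\n", nrow(x$effects)))
  if (nrow(x$effects) > 0)
    print(utils::head(x$effects[c("name", "folds_selected",
                                  "mean_norm_importance", "direction",
                                  "signed_effect")], 10))
  invisible(x)
}
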