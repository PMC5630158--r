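# normalized importance: raw importances divided by the model's maximum;
# all-zero importances (e.g. constant target) stay zero.
normalize_importance <- function(raw) {
  mx <- max(raw)
  if (mx <= 0) {
    warning("all feature importances are zero")
    return(raw * 0)
  }
  raw / mx
}

#' Normalized feature importances of one fold model
#'
#' Raw impurity (variance-reduction) importances divided by the fold's
#' maximum, so the strongest feature of every model scores 1 and
#' importances are comparable across models with different feature counts.
#'
#' @param fold an `ires_fold_model` (element of an `ires_cv_result`).
#' @return named numeric vector of normalized importances in `[0, 1]`.
#' @export
fold_importances <- function(fold) {
  normalize_importance(fold$importance)
}

#' Aggregate importances across outer CV folds
#'
#' @param cv an `ires_cv_result` (or list of fold models).
#' @return data.frame with one row per feature ever pre-selected:
#'   `feature`, `folds_selected` (number of folds whose pre-selection
#'   retained it), `mean_norm_importance` (mean over those folds).  The
#'   per-fold importance matrix (features x folds, `NA` where a feature was
#'   not selected) is attached as attribute `"per_fold"`.
#' @export
aggregate_importances <- function(cv) {
  folds <- if (inherits(cv, "ires_cv_result")) cv$folds else cv
  if (length(folds) == 0) stop("no fold models")
  per <- lapply(folds, fold_importances)
  feats <- unique(unlist(lapply(per, names)))
  mat <- matrix(NA_real_, length(feats), length(per),
                dimnames = list(feats, NULL))
  for (j in seq_along(per)) mat[names(per[[j]]), j] <- per[[j]]
  out <- data.frame(
    feature = feats,
    folds_selected = rowSums(!is.na(mat)),
    mean_norm_importance = rowMeans(mat, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_fold") <- mat
  out
}

#' Partial dependence of the cross-validated model on one feature
#'
#' For every observed value v of the feature, the expected prediction is
#' approximated by substituting v into that feature's column for all
#' training samples of a fold and averaging the fold model's predictions;
#' curves are then averaged across the folds whose pre-selection retained
#' the feature.
#'
#' @param cv an `ires_cv_result`.
#' @param feature feature name (a `descriptors$name` entry).
#' @param grid optional value grid; defaults to the sorted unique observed
#'   values of the feature over all samples.
#' @return an `ires_pd` list: `feature`, `values` (grid), `ybar` (averaged
#'   expected predictions), `per_fold` (fold x grid matrix),
#'   `folds_used`.
#' @export
partial_dependence <- function(cv, feature, grid = NULL) {
  stopifnot(inherits(cv, "ires_cv_result"))
  col <- match(feature, cv$matrix$descriptors$name)
  if (is.na(col)) stop("unknown feature: ", feature)
  if (is.null(grid))
    grid <- sort(unique(cv$matrix$values[, col]))
  use <- which(vapply(cv$folds, function(f) feature %in% f$features,
                      logical(1)))
  if (length(use) == 0) stop("feature pre-selected in no fold: ", feature)
  per <- matrix(NA_real_, length(use), length(grid))
  for (fi in seq_along(use)) {
    f <- cv$folds[[use[fi]]]
    X <- as.matrix(cv$matrix$values[f$train_idx, f$features, drop = FALSE])
    jc <- match(feature, f$features)
    for (vi in seq_along(grid)) {
      X[, jc] <- grid[vi]
      per[fi, vi] <- mean(predict_model(f$ensemble, X))
    }
  }
  structure(list(feature = feature, values = grid, ybar = colMeans(per),
                 per_fold = per, folds_used = use), class = "ires_pd")
}

#' Directionality of a partial dependence curve
#'
#' A feature is classified as positive (increasing IRES activity) if the
#' average of the finite-difference slopes between consecutive grid points
#' is positive, and negative otherwise (flat or single-point curves are
#' negative by this rule).
#'
#' @param pd an `ires_pd` from [partial_dependence()] (or a list with
#'   `values` and `ybar`).
#' @return `"positive"` or `"negative"`.
#' @export
classify_direction <- function(pd) {
  v <- pd$values
  y <- pd$ybar
  if (length(v) < 2) return("negative")
  slopes <- diff(y) / diff(v)
  if (mean(slopes) > 0) "positive" else "negative"
}

#' Robust and predictive feature effects
#'
#' Selects the features that are robust (pre-selected in every outer CV
#' fold) and predictive (mean normalized importance at least `threshold`),
#' determines each one's directionality from its partial dependence, and
#' reports the signed effect (mean normalized importance with the sign of
#' the direction).
#'
#' @param cv an `ires_cv_result`.
#' @param threshold minimum mean normalized importance (default 0.1).
#' @return data.frame of feature effects: descriptor columns plus
#'   `folds_selected`, `mean_norm_importance`, `direction`,
#'   `signed_effect`.
#' @export
feature_effects <- function(cv, threshold = 0.1) {
  prof <- aggregate_importances(cv)
  keep <- prof[prof$folds_selected == length(cv$folds) &
                 prof$mean_norm_importance >= threshold, , drop = FALSE]
  desc <- cv$matrix$descriptors
  out <- cbind(desc[match(keep$feature, desc$name),
                    c("name", "kmer", "scope", "window_start", "window_end")],
               keep[c("folds_selected", "mean_norm_importance")])
  out$direction <- vapply(out$name, function(f)
    classify_direction(partial_dependence(cv, f)), character(1))
  out$signed_effect <- ifelse(out$direction == "positive", 1, -1) *
    out$mean_norm_importance
  rownames(out) <- NULL
  out[order(-abs(out$signed_effect)), , drop = FALSE]
}

#' Low-level robust/predictive selection
#'
#' Applies the robustness (selected in all folds) and predictiveness
#' (mean normalized importance >= `threshold`) criteria to an aggregated
#' importance profile, attaching externally supplied directions.
#'
#' @param profiles output of [aggregate_importances()].
#' @param n_folds total number of folds that define robustness.
#' @param directions named character vector (`"positive"`/`"negative"`)
#'   per feature.
#' @param threshold minimum mean normalized importance (default 0.1).
#' @return data.frame with `feature`, `folds_selected`,
#'   `mean_norm_importance`, `direction`, `signed_effect`.
#' @export
select_robust_predictive <- function(profiles, n_folds, directions,
                                     threshold = 0.1) {
  keep <- profiles[profiles$folds_selected == n_folds &
                     profiles$mean_norm_importance >= threshold, ,
                   drop = FALSE]
  keep$direction <- unname(directions[keep$feature])
  keep$signed_effect <- ifelse(keep$direction == "positive", 1, -1) *
    keep$mean_norm_importance
  rownames(keep) <- NULL
  keep
}

#' Common and unique features across sequence groups
#'
#' @param effects_by_group named list (group -> feature-effect data.frame
#'   from [feature_effects()]).
#' @return list with `common` (features selected in >= 2 groups) and
#'   `unique` (features selected in exactly 1), each a data.frame of
#'   `feature` and the supporting `groups` (comma-joined).
#' @export
common_and_unique <- function(effects_by_group) {
  stopifnot(length(effects_by_group) >= 2, !is.null(names(effects_by_group)))
  tab <- do.call(rbind, lapply(names(effects_by_group), function(g) {
    ef <- effects_by_group[[g]]
    if (nrow(ef) == 0) return(NULL)
    data.frame(feature = ef$name, group = g, stringsAsFactors = FALSE)
  }))
  if (is.null(tab))
    return(list(common = data.frame(feature = character(0),
                                    groups = character(0)),
                unique = data.frame(feature = character(0),
                                    groups = character(0))))
  agg <- stats::aggregate(group ~ feature, tab,
                          FUN = function(g) paste(sort(g), collapse = ","))
  k <- vapply(strsplit(agg$group, ","), length, integer(1))
  names(agg)[2] <- "groups"
  list(common = agg[k >= 2, , drop = FALSE],
       unique = agg[k == 1, , drop = FALSE])
}

#' Positional effect islands of one k-mer
#'
#' Maximal runs of consecutive robust windows (adjacent window start labels
#' at the configured step) of length >= 2 form islands.
#'
#' @param window_effects data.frame with `window_start` and `signed_effect`
#'   for the robust positional features of one k-mer in one group.
#' @param step window grid step in nt (default 10).
#' @param window_len window length in nt (default 20).
#' @return data.frame of islands: `start`, `end` (AUG-relative interval
#'   covered), `n_windows`, `mean_signed_effect`.
#' @export
find_islands <- function(window_effects, step = 10, window_len = 20) {
  if (nrow(window_effects) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      n_windows = integer(0),
                      mean_signed_effect = numeric(0)))
  we <- window_effects[order(window_effects$window_start), , drop = FALSE]
  run <- cumsum(c(1, diff(we$window_start) != step))
  out <- do.call(rbind, lapply(split(we, run), function(blk) {
    data.frame(start = min(blk$window_start),
               end = max(blk$window_start) + window_len,
               n_windows = nrow(blk),
               mean_signed_effect = mean(blk$signed_effect))
  }))
  out <- out[out$n_windows >= 2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus positional effects across groups
#'
#' For each window, if at least two groups carry a robust effect of the
#' same sign there, the consensus is that sign with magnitude equal to the
#' largest supporting absolute effect; windows without such agreement get
#' no consensus.  (If both signs were supported by >= 2 groups, the sign
#' with the larger maximal effect wins.)
#'
#' @param group_window_effects data.frame with `group`, `window_start`,
#'   `signed_effect` for the robust positional features of one k-mer.
#' @return data.frame with `window_start`, `consensus` (signed effect, `NA`
#'   when unsupported), `supporting_groups` (comma-joined).
#' @export
consensus_effects <- function(group_window_effects) {
  sp <- split(group_window_effects, group_window_effects$window_start)
  out <- do.call(rbind, lapply(sp, function(blk) {
    res <- data.frame(window_start = blk$window_start[1],
                      consensus = NA_real_,
                      supporting_groups = NA_character_)
    for (sgn in c(1, -1)) {
      sup <- blk[sign(blk$signed_effect) == sgn, , drop = FALSE]
      if (length(unique(sup$group)) >= 2) {
        cand <- sgn * max(abs(sup$signed_effect))
        if (is.na(res$consensus) || abs(cand) > abs(res$consensus)) {
          res$consensus <- cand
          res$supporting_groups <- paste(sort(unique(sup$group)),
                                         collapse = ",")
        }
      }
    }
    res
  }))
  rownames(out) <- NULL
  out[order(out$window_start), , drop = FALSE]
}

#' GC-content comparison between two sequence groups
#'
#' Per-sequence GC fraction with a two-sided Wilcoxon rank-sum test.
#'
#' @param seqs_a,seqs_b character vectors of RNA sequences.
#' @return list with `gc_a`, `gc_b` (per-sequence GC fractions),
#'   `statistic` (rank-sum W) and `p`.
#' @export
gc_content_compare <- function(seqs_a, seqs_b) {
  stopifnot(length(seqs_a) > 0, length(seqs_b) > 0)
  gc <- function(s) {
    (nchar(s) - nchar(gsub("[GC]", "", s))) / nchar(s)
  }
  ga <- gc(seqs_a)
  gb <- gc(seqs_b)
  wt <- suppressWarnings(stats::wilcox.test(ga, gb, exact = FALSE))
  list(gc_a = ga, gc_b = gb, statistic = unname(wt$statistic),
       p = wt$p.value)
}
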