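# Shared internals for feature screening -------------------------------------

# Ranks of y and the tie-correction term sum(t^3 - t) over tie groups.
y_rank_info <- function(y) {
  r <- rank(y)
  tt <- table(y)
  list(rank = r, tie_term = sum(tt^3 - tt))
}

# Column-wise association of a sparse feature matrix with activity.
assoc_matrix <- function(values, activity,
                         representation = c("count", "presence")) {
  representation <- match.arg(representation)
  stopifnot(nrow(values) == length(activity))
  values <- methods::as(values, "CsparseMatrix")
  yi <- y_rank_info(activity)
  .assoc_columns(values@p, values@i, values@x, nrow(values), yi$rank,
                 yi$tie_term, representation == "presence")
}

#' Association between one feature and IRES activity
#'
#' Count features are scored by the Spearman rank correlation between
#' feature values and activity (two-sided p, t approximation, appropriate
#' under the heavy ties of count data).  Presence features are scored by
#' the two-sided Mann-Whitney U test comparing activity of sequences with
#' and without the k-mer (normal approximation with tie and continuity
#' correction).  A zero-variance feature has an undefined statistic and is
#' reported with `p = 1`.
#'
#' @param values numeric feature vector (non-negative).
#' @param activity numeric activity vector of the same length.
#' @param representation `"count"` or `"presence"`.
#' @return list with `statistic` (Spearman rho or Mann-Whitney U), `p`, and
#'   `prevalence` (fraction of non-zero values).
#' @export
associate <- function(values, activity,
                      representation = c("count", "presence")) {
  stopifnot(length(values) == length(activity), length(values) >= 3)
  res <- assoc_matrix(Matrix::Matrix(values, ncol = 1, sparse = TRUE),
                      activity, representation)
  list(statistic = res$statistic[1], p = res$p[1],
       prevalence = res$prevalence[1])
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param ps numeric vector of p-values in `[0, 1]`.
#' @param fdr target false discovery rate.
#' @return list with `q` (BH-adjusted p-values, monotone-enforced) and
#'   `rejected` (`q <= fdr`).
#' @export
benjamini_hochberg <- function(ps, fdr = 0.05) {
  stopifnot(all(ps >= 0 & ps <= 1, na.rm = TRUE), fdr > 0, fdr < 1)
  if (length(ps) == 0)
    return(list(q = numeric(0), rejected = logical(0)))
  q <- stats::p.adjust(ps, method = "BH")
  list(q = q, rejected = q <= fdr)
}

#' Screen features by association with activity
#'
#' Keeps the features whose association with activity is significant at the
#' given FDR (Benjamini-Hochberg over all candidate features jointly) and
#' that are present (non-zero) in at least `min_prevalence` of the
#' sequences of the partition used for screening.  Column order is
#' preserved.  Pre-selection is meant to be recomputed on every training
#' partition it serves, so held-out data never influence it.
#'
#' @param fm an `ires_feature_matrix` (rows = the training partition).
#' @param activity activity vector aligned with the rows of `fm`.
#' @param fdr false discovery rate for the BH step (default 0.05).
#' @param min_prevalence minimum fraction of sequences with a non-zero
#'   feature value (default 0.10).
#' @return list with `matrix` (the reduced `ires_feature_matrix`) and
#'   `results` (data.frame: feature descriptor columns plus `statistic`,
#'   `p`, `q`, `prevalence`, `kept`).
#' @export
preselect <- function(fm, activity, fdr = 0.05, min_prevalence = 0.10) {
  stopifnot(inherits(fm, "ires_feature_matrix"),
            nrow(fm$values) == length(activity),
            min_prevalence >= 0, min_prevalence < 1)
  res <- assoc_matrix(fm$values, activity, fm$config$representation)
  bh <- benjamini_hochberg(res$p, fdr)
  out <- cbind(fm$descriptors,
               data.frame(statistic = res$statistic, p = res$p, q = bh$q,
                          prevalence = res$prevalence,
                          kept = bh$rejected & res$prevalence >= min_prevalence))
  red <- subset_cols(fm, out$name[out$kept])
  if (sum(out$kept) == 0)
    warning("no feature survived pre-selection")
  list(matrix = red, results = out)
}
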