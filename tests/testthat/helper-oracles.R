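# Independent reference implementations used as oracles, plus small fixture
# builders.  Everything here is deliberately naive and separate from the
# package's code paths.

# step-up BH reference: largest k with p_(k) <= k/m * q is the rejection
# cutoff; adjusted values are the monotone-enforced p * m / rank.
bh_stepup_ref <- function(ps, fdr) {
  m <- length(ps)
  o <- order(ps)
  ranked <- ps[o] * m / seq_len(m)
  q <- rev(cummin(rev(ranked)))
  q <- pmin(q, 1)
  qs <- numeric(m)
  qs[o] <- q
  cutoff <- which(ps[o] <= seq_len(m) / m * fdr)
  rejected <- logical(m)
  if (length(cutoff) > 0)
    rejected[o[seq_len(max(cutoff))]] <- TRUE
  list(q = qs, rejected = rejected)
}

# exhaustive pairwise AUC-ROC oracle (ties count 1/2)
auc_pairwise_ref <- function(labels, scores) {
  sp <- scores[labels]
  sn <- scores[!labels]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# step-integrated AUC-PR oracle over distinct thresholds
auc_pr_ref <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  n1 <- sum(labels)
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels & sel) / sum(sel)
    rec <- sum(labels & sel) / n1
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# random RNA string from the current RNG stream
random_rna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# minimal valid library from explicit sequences
tiny_library <- function(rna, activity, group = "dsrna", threshold = 1) {
  ires_library(sprintf("s%03d", seq_along(rna)), rna,
               rep_len(group, length(rna)), activity, threshold)
}

# a cv-result-shaped object around plain-function "ensembles", for
# interpretation tests that do not need real training
mock_cv <- function(values, folds) {
  structure(list(
    folds = folds,
    matrix = list(values = values,
                  descriptors = data.frame(name = colnames(values),
                                           stringsAsFactors = FALSE)),
    records = NULL), class = "ires_cv_result")
}

mock_fold <- function(fun, features, train_idx, importance = NULL) {
  structure(list(fold = 1, ensemble = fun, features = features,
                 train_idx = train_idx,
                 importance = importance), class = "ires_fold_model")
}
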