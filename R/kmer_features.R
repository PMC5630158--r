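#' Featurization settings for k-mer matrices
#'
#' Controls how RNA sequences are turned into k-mer features: cumulative
#' k-mer lengths 1..`k_max` (the interpreted models mix lengths, so all
#' shorter k-mers are included), recorded globally over the whole sequence
#' and/or in moving windows anchored at the start AUG (default 20nt windows
#' advancing 5'-ward in 10nt steps, i.e. overlapping by 10nt).  The
#' `presence` representation caps every count at 1.
#'
#' @param k_max maximum k-mer length (1..5; the analyses interpret k = 4).
#' @param window_len positional window length in nt.
#' @param step window step in nt (`window_len - step` = overlap).
#' @param representation `"count"` (overlapping occurrence counts) or
#'   `"presence"` (counts capped at 1).
#' @param include_global,include_positional which feature blocks to build.
#' @return a `featurization_config` list.
#' @export
featurization_config <- function(k_max = 4, window_len = 20, step = 10,
                                 representation = c("count", "presence"),
                                 include_global = TRUE,
                                 include_positional = TRUE) {
  representation <- match.arg(representation)
  stopifnot(k_max >= 1, k_max <= 5, step >= 1, step <= window_len,
            window_len >= k_max)
  if (!include_global && !include_positional)
    stop("at least one of the global/positional blocks must be enabled")
  structure(list(k_max = as.integer(k_max), window_len = as.integer(window_len),
                 step = as.integer(step), representation = representation,
                 include_global = include_global,
                 include_positional = include_positional),
            class = "featurization_config")
}

#' Enumerate all k-mers up to a maximum length
#'
#' @param k_max maximum length (1..5).
#' @return character vector of all 4 + 16 + ... + 4^`k_max` k-mers, ordered
#'   by length then lexicographically (A < C < G < U).
#' @export
enumerate_kmers <- function(k_max) {
  stopifnot(k_max >= 1, k_max <= 5)
  b <- c("A", "C", "G", "U")
  out <- character(0)
  cur <- b
  for (k in seq_len(k_max)) {
    out <- c(out, cur)
    if (k < k_max) cur <- as.vector(t(outer(cur, b, paste0)))
  }
  out
}

#' Count occurrences of a k-mer in a sequence
#'
#' Overlapping occurrences are counted (e.g. "AA" occurs 3 times in
#' "AAAA").  A k-mer longer than the sequence has count 0.
#'
#' @param rna RNA sequence string.
#' @param kmer k-mer string.
#' @return integer occurrence count.
#' @export
count_global <- function(rna, kmer) {
  k <- nchar(kmer)
  n <- nchar(rna)
  if (k > n) return(0L)
  s <- seq_len(n - k + 1)
  sum(substring(rna, s, s + k - 1) == kmer)
}

#' AUG-anchored positional windows for a sequence
#'
#' Windows are given in AUG-relative coordinates (0-based, half-open;
#' position 0 is the first base of the start AUG, negative positions are
#' upstream).  The first window is `[-window_len, 0)` and windows advance
#' 5'-ward by `step` while fully contained in the sequence; a partial 5'
#' window is dropped.
#'
#' @param rna_length sequence length in nt.
#' @param aug_offset AUG anchor (bases 5' of the AUG); defaults to the full
#'   length.
#' @param cfg a [featurization_config()].
#' @return data.frame with columns `start`, `end` (AUG-relative, half-open),
#'   ordered from the AUG outward; zero rows (with a warning) if no window
#'   fits.
#' @export
windows_for <- function(rna_length, aug_offset = rna_length,
                        cfg = featurization_config()) {
  stopifnot(aug_offset >= 1, aug_offset <= rna_length)
  if (aug_offset < cfg$window_len) {
    warning("sequence upstream extent shorter than one window")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  n_win <- (aug_offset - cfg$window_len) %/% cfg$step + 1L
  start <- -cfg$window_len - cfg$step * (seq_len(n_win) - 1L)
  data.frame(start = start, end = start + cfg$window_len)
}

#' Count k-mer occurrences inside one AUG-relative window
#'
#' An occurrence belongs to a window iff its full extent `[p, p + k)` lies
#' inside the window interval.
#'
#' @param rna RNA sequence string.
#' @param kmer k-mer string.
#' @param window length-2 numeric, the half-open AUG-relative interval
#'   `[start, end)`.
#' @param aug_offset AUG anchor; defaults to the sequence length.
#' @return integer occurrence count within the window.
#' @export
count_windowed <- function(rna, kmer, window, aug_offset = nchar(rna)) {
  k <- nchar(kmer)
  n <- nchar(rna)
  if (k > n) return(0L)
  s0 <- 0:(n - k)                       # 0-based occurrence starts
  p <- s0 - aug_offset                  # AUG-relative
  inside <- p >= window[1] & (p + k) <= window[2]
  if (!any(inside)) return(0L)
  s <- s0[inside] + 1L
  sum(substring(rna, s, s + k - 1) == kmer)
}

feature_name <- function(kmer, scope, start = NA, end = NA) {
  ifelse(scope == "global", paste0(kmer, "|global"),
         sprintf("%s|[%d,%d)", kmer, start, end))
}

#' Build the k-mer feature matrix for a library
#'
#' Columns are the global block (every k-mer up to `k_max`, ordered by
#' length then lexicographically) followed by the positional block ordered
#' window-major from the AUG outward.  Windows are labelled by AUG-relative
#' coordinates so sequences of different lengths share columns; a sequence
#' lacking a window contributes 0 there.  Under the `presence`
#' representation all counts are capped at 1.
#'
#' @param records an `ires_library` (or data.frame with `rna`,
#'   `aug_offset`, `id`).
#' @param cfg a [featurization_config()].
#' @return an `ires_feature_matrix`: list with `values` (sparse
#'   [Matrix::dgCMatrix-class], samples x features), `descriptors`
#'   (data.frame: `name`, `kmer`, `scope`, `window_start`, `window_end`,
#'   `representation`), `sample_ids` and `config`.
#' @export
build_matrix <- function(records, cfg = featurization_config()) {
  stopifnot(nrow(records) > 0)
  kmers <- enumerate_kmers(cfg$k_max)
  nk <- length(kmers)

  n_win <- 0L
  if (cfg$include_positional) {
    up <- records$aug_offset
    n_win <- max(0L, (max(up) - cfg$window_len) %/% cfg$step + 1L)
    if (max(up) < cfg$window_len) n_win <- 0L
    if (n_win == 0L)
      warning("no sequence accommodates a positional window; ",
              "positional block is empty")
  }

  tri <- .kmer_triplets(records$rna, as.integer(records$aug_offset),
                        cfg$k_max, cfg$window_len, cfg$step,
                        cfg$include_global, cfg$include_positional, n_win)
  M <- (if (cfg$include_global) nk else 0L) + n_win * nk

  desc <- data.frame(kmer = character(0), scope = character(0),
                     window_start = integer(0), window_end = integer(0))
  if (cfg$include_global)
    desc <- data.frame(kmer = kmers, scope = "global",
                       window_start = NA_integer_, window_end = NA_integer_)
  if (n_win > 0L) {
    ws <- -cfg$window_len - cfg$step * (seq_len(n_win) - 1L)
    desc <- rbind(desc, data.frame(
      kmer = rep(kmers, times = n_win),
      scope = "window",
      window_start = rep(ws, each = nk),
      window_end = rep(ws + cfg$window_len, each = nk)))
  }
  desc$representation <- cfg$representation
  desc$name <- feature_name(desc$kmer, desc$scope, desc$window_start,
                            desc$window_end)
  desc <- desc[c("name", "kmer", "scope", "window_start", "window_end",
                 "representation")]

  x <- as.numeric(tri$x)
  if (cfg$representation == "presence") x <- pmin(x, 1)
  values <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = x,
                                 dims = c(nrow(records), M),
                                 dimnames = list(records$id, desc$name))
  structure(list(values = values, descriptors = desc,
                 sample_ids = records$id, config = cfg),
            class = "ires_feature_matrix")
}

#' @export
dim.ires_feature_matrix <- function(x) dim(x$values)

#' @export
print.ires_feature_matrix <- function(x, ...) {
  cat(sprintf("ires_feature_matrix: %d samples x %d features (%s, k <= %d)\n",
              nrow(x$values), ncol(x$values), x$config$representation,
              x$config$k_max))
  invisible(x)
}

# Row subset of a feature matrix, keeping descriptors/config.
subset_rows <- function(fm, idx) {
  structure(list(values = fm$values[idx, , drop = FALSE],
                 descriptors = fm$descriptors,
                 sample_ids = fm$sample_ids[idx], config = fm$config),
            class = "ires_feature_matrix")
}

# Column subset (by name), keeping alignment between values and descriptors.
subset_cols <- function(fm, names) {
  keep <- match(names, fm$descriptors$name)
  stopifnot(!anyNA(keep))
  structure(list(values = fm$values[, keep, drop = FALSE],
                 descriptors = fm$descriptors[keep, , drop = FALSE],
                 sample_ids = fm$sample_ids, config = fm$config),
            class = "ires_feature_matrix")
}
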