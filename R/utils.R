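#' Derive a child seed from a master seed
#'
#' Deterministic splitter used to hand independent seeds to nested
#' randomized steps (fold assignment, per-model training, barcode sampling)
#' from one user-facing master seed.  A linear congruential mix keeps the
#' result a strictly positive 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param offset integer stream label; different offsets give different,
#'   reproducible child seeds.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483629
  as.integer(((abs(seed) %% m) * 48271 + (abs(offset) %% m) * 16807 + 1) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character strings of equal length.
#' @return integer number of differing positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# uppercase + DNA->RNA transliteration
as_rna <- function(x) chartr("t", "U", chartr("T", "U", toupper(x)))

# TRUE for strings over the ACGU alphabet only (non-empty)
is_valid_rna <- function(x) nchar(x) > 0 & !grepl("[^ACGU]", x)
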