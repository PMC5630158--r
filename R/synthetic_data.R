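#' Specification of a planted activity motif
#'
#' A motif contributes `effect_size` activity units for every occurrence,
#' weighted by a Gaussian positional profile: an occurrence whose
#' AUG-relative start is p contributes
#' `effect_size * exp(-(p - position_center)^2 / (2 * position_width^2))`.
#' An infinite width (or `NA` center) makes the effect global.
#'
#' @param motif RNA string (length <= 8).
#' @param effect_size activity units per occurrence (sign = direction).
#' @param position_center AUG-relative position of maximal effect (`NA`
#'   for a global effect).
#' @param position_width Gaussian s.d. in nt (`Inf` for a global effect).
#' @return a `motif_spec` list.
#' @export
motif_spec <- function(motif, effect_size, position_center = NA,
                       position_width = Inf) {
  motif <- as_rna(motif)
  stopifnot(is_valid_rna(motif), nchar(motif) <= 8, position_width > 0)
  structure(list(motif = motif, effect_size = effect_size,
                 position_center = position_center,
                 position_width = position_width), class = "motif_spec")
}

#' Default per-group motif recipes
#'
#' Every group carries a U-rich positive motif with its strongest effect
#' about 50nt upstream of the AUG and an A-rich global negative motif,
#' mirroring the qualitative contrasts the analysis is meant to recover;
#' the retroviral group additionally carries a C-rich positive motif
#' acting far upstream.
#'
#' @return named list (group -> list of [motif_spec()]s).
#' @export
default_recipes <- function() {
  base <- list(motif_spec("UUUU", 1.0, position_center = -50,
                          position_width = 20),
               motif_spec("AAAA", -0.8))
  rec <- lapply(ires_groups(), function(g) base)
  names(rec) <- ires_groups()
  rec$retro <- c(base, list(motif_spec("CCCC", 1.0, position_center = -200,
                                       position_width = 25)))
  rec
}

#' Synthetic library settings
#'
#' Defaults emulate the statistical shape of the measured library: 174nt
#' sequences whose 3' end abuts the reporter start AUG, a strongly
#' right-skewed activity distribution produced by left-censoring latent
#' activities at their `floor_quantile` (0.89, so about 11% of sequences
#' are active above the detection floor), group-specific planted motifs
#' with position-dependent effects, and additive Gaussian measurement
#' noise.
#'
#' @param n library size (>= 10).
#' @param length sequence length in nt (default 174).
#' @param group_weights named non-negative weights over [ires_groups()]
#'   (default equal).
#' @param recipes named list of [motif_spec()] lists per group.
#' @param gc base GC fraction of the background sequences.
#' @param baseline latent activity baseline.
#' @param noise_sd additive Gaussian noise s.d.
#' @param plant_prob probability that each recipe motif is explicitly
#'   planted in a sequence (motifs also arise by chance).
#' @param floor_quantile latent-activity quantile defining the detection
#'   floor.
#' @param seed RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n = 2000, length = 174, group_weights = NULL,
                             recipes = default_recipes(), gc = 0.5,
                             baseline = 0, noise_sd = 0.25,
                             plant_prob = 0.35, floor_quantile = 0.89,
                             seed = 1) {
  stopifnot(n >= 10, length >= 20, gc >= 0, gc <= 1,
            floor_quantile > 0, floor_quantile < 1,
            plant_prob >= 0, plant_prob <= 1, noise_sd >= 0)
  if (is.null(group_weights))
    group_weights <- stats::setNames(rep(1, 7), ires_groups())
  stopifnot(setequal(names(group_weights), ires_groups()),
            all(group_weights >= 0), sum(group_weights) > 0)
  structure(list(n = as.integer(n), length = as.integer(length),
                 group_weights = group_weights, recipes = recipes, gc = gc,
                 baseline = baseline, noise_sd = noise_sd,
                 plant_prob = plant_prob, floor_quantile = floor_quantile,
                 seed = seed), class = "synthetic_config")
}

#' Draw a random RNA sequence
#'
#' I.i.d. letters with `P(G) = P(C) = gc/2` and `P(A) = P(U) = (1-gc)/2`.
#' Uses the current RNG stream.
#'
#' @param length sequence length.
#' @param gc GC fraction in `[0, 1]`.
#' @return RNA string.
#' @export
generate_sequence <- function(length, gc = 0.5) {
  stopifnot(gc >= 0, gc <= 1)
  paste(sample(c("A", "C", "G", "U"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# AUG-relative start positions of all (overlapping) motif occurrences.
motif_occurrences <- function(rna, motif, aug_offset = nchar(rna)) {
  k <- nchar(motif)
  n <- nchar(rna)
  if (k > n) return(integer(0))
  s <- seq_len(n - k + 1)
  hit <- substring(rna, s, s + k - 1) == motif
  (s[hit] - 1L) - aug_offset
}

# Positional Gaussian weight of an occurrence at AUG-relative position p.
motif_weight <- function(p, spec) {
  if (is.na(spec$position_center) || is.infinite(spec$position_width))
    return(rep(1, length(p)))
  exp(-(p - spec$position_center)^2 / (2 * spec$position_width^2))
}

#' Latent activity of one sequence under a motif recipe
#'
#' `baseline` plus, for every occurrence of every recipe motif, its effect
#' size weighted by the Gaussian positional profile, plus Gaussian noise
#' (drawn from the current RNG stream).
#'
#' @param rna RNA string.
#' @param specs list of [motif_spec()]s.
#' @param baseline latent baseline.
#' @param noise_sd additive noise s.d. (0 for none).
#' @param aug_offset AUG anchor (default: sequence length).
#' @return numeric latent activity.
#' @export
latent_activity <- function(rna, specs, baseline = 0, noise_sd = 0,
                            aug_offset = nchar(rna)) {
  eff <- 0
  for (spec in specs) {
    p <- motif_occurrences(rna, spec$motif, aug_offset)
    if (length(p) > 0)
      eff <- eff + spec$effect_size * sum(motif_weight(p, spec))
  }
  noise <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
  baseline + eff + noise
}

#' Generate a synthetic IRES library with ground truth
#'
#' Sequences are drawn per group recipe; each recipe motif is additionally
#' planted (substituted) with probability `plant_prob` at a position drawn
#' from its Gaussian positional profile (uniformly for global motifs).
#' Latent activities follow [latent_activity()]; the detection floor is
#' the `floor_quantile` of the latent activities and observed activity is
#' `max(latent, floor)`, producing the left-censored, right-skewed
#' distribution of the assay.  Deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `records` (an `ires_library`), `threshold` (the
#'   floor), and `ground_truth` (list: `sequences` data.frame with latent
#'   and observed activity per sequence, `planted` data.frame of explicit
#'   plantings).
#' @export
generate_library <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  w <- cfg$group_weights / sum(cfg$group_weights)
  n_per <- floor(cfg$n * w)
  rem <- cfg$n - sum(n_per)
  if (rem > 0) {
    top <- order(cfg$n * w - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[top] <- n_per[top] + 1
  }
  groups <- rep(names(n_per), n_per)

  with_seed(cfg$seed, {
    rna <- character(cfg$n)
    planted <- list()
    for (i in seq_len(cfg$n)) {
      s <- generate_sequence(cfg$length, cfg$gc)
      for (spec in cfg$recipes[[groups[i]]]) {
        if (stats::runif(1) < cfg$plant_prob) {
          k <- nchar(spec$motif)
          lo <- -cfg$length
          hi <- -k
          pos <- if (is.na(spec$position_center) ||
                     is.infinite(spec$position_width))
            floor(stats::runif(1, lo, hi + 1))
          else
            round(stats::rnorm(1, spec$position_center,
                               spec$position_width))
          pos <- min(max(pos, lo), hi)
          a <- pos + cfg$length + 1L # 1-based start in the string
          substr(s, a, a + k - 1L) <- spec$motif
          planted[[length(planted) + 1]] <-
            data.frame(idx = i, motif = spec$motif, position = pos)
        }
      }
      rna[i] <- s
    }
    latent <- vapply(seq_len(cfg$n), function(i)
      latent_activity(rna[i], cfg$recipes[[groups[i]]], cfg$baseline,
                      cfg$noise_sd), numeric(1))
    if (stats::var(latent) == 0) stop("degenerate library: constant latent activity")
    floor_v <- unname(stats::quantile(latent, cfg$floor_quantile))
    observed <- pmax(latent, floor_v)
    ids <- sprintf("syn%05d", seq_len(cfg$n))
    records <- ires_library(ids, rna, groups, observed, threshold = floor_v)
    planted <- if (length(planted)) do.call(rbind, planted)
    else data.frame(idx = integer(0), motif = character(0),
                    position = integer(0))
    planted$id <- ids[planted$idx]
    gt <- list(sequences = data.frame(id = ids, group = groups,
                                      latent = latent, observed = observed,
                                      active = observed > floor_v),
               planted = planted[c("id", "motif", "position")])
    list(records = records, threshold = floor_v, ground_truth = gt)
  })
}
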