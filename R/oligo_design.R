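# The spacer background: a 9-mer previously used as inert spacer between
# IRES element copies (Spacer1, TTCTGACAT as DNA), concatenated and
# truncated to the 164nt variable-region length.
SPACER_UNIT <- "UUCUGACAU"

# Synthetic stand-in for the native 164nt HBB (beta-globin) negative-control
# fragment.  The authentic fragment is not redistributed here; this fixed
# placeholder has HBB-like base composition, no TEV element match, and is
# labelled synthetic wherever it appears.
HBB_LIKE_SYNTHETIC <- paste0(
  "AGUUGGUACUCAGCCGGCAUUGAUUCAGCACCCCGCCUAUCUAGUGGUAGCCUCCAAUAG",
  "ACCCAGUAGUUUCCCCGCACCAGACGUUUCCGUAAUGAUGCUCAGAUAAUUCCAAACUCG",
  "GAGAUAAGCACUAUGGUCGCCAGCACGCAGACCUCAGCUUCAUC")

#' Construct an oligo design background
#'
#' A background is a 164nt IRES-inactive variable-region sequence with 8
#' predefined, non-overlapping element sites (0-based start coordinates;
#' each site spans the 7nt of the planted element).
#'
#' @param name background label.
#' @param sequence 164nt RNA string.
#' @param site_starts 0-based start coordinates of the element sites.
#' @param element_len length of the planted element (default 7).
#' @return an `ires_background` list.
#' @export
design_background <- function(name, sequence,
                              site_starts = seq(2L, 142L, by = 20L),
                              element_len = 7L) {
  sequence <- as_rna(sequence)
  stopifnot(nchar(sequence) == 164, is_valid_rna(sequence))
  site_starts <- sort(as.integer(site_starts))
  stopifnot(all(site_starts >= 0),
            all(site_starts <= 164 - element_len))
  if (any(diff(site_starts) < element_len))
    stop("element sites overlap")
  structure(list(name = name, sequence = sequence,
                 site_starts = site_starts,
                 element_len = as.integer(element_len)),
            class = "ires_background")
}

#' The two shipped design backgrounds
#'
#' `spacer_synthetic`: a truncated concatenation of the inert 9nt spacer
#' unit.  `hbb_synthetic`: a synthetic placeholder with the base
#' composition of the native HBB beta-globin negative-control fragment
#' (the authentic fragment is a configuration input; pass your own via
#' [design_background()]).
#'
#' @param site_starts 0-based site coordinates shared by both backgrounds
#'   (default: 8 evenly spaced sites at 2, 22, ..., 142).
#' @return named list of two `ires_background`s.
#' @export
tev_backgrounds <- function(site_starts = seq(2L, 142L, by = 20L)) {
  spacer <- substr(strrep(SPACER_UNIT, ceiling(164 / nchar(SPACER_UNIT))),
                   1, 164)
  list(
    spacer_synthetic = design_background("spacer_synthetic", spacer,
                                         site_starts),
    hbb_synthetic = design_background("hbb_synthetic", HBB_LIKE_SYNTHETIC,
                                      site_starts))
}

#' Enumerate element placements
#'
#' All subsets of the available sites, including the empty placement (the
#' 0-site oligo belongs to the "0-1" bin of the analysis), in deterministic
#' bitmask order.
#'
#' @param n_sites number of available sites (<= 16).
#' @return list of integer vectors (site indices, 1-based; possibly empty).
#' @export
enumerate_placements <- function(n_sites = 8) {
  stopifnot(n_sites >= 0, n_sites <= 16)
  lapply(0:(2^n_sites - 1), function(mask)
    which(bitwAnd(mask, bitwShiftL(1, seq_len(n_sites) - 1)) > 0))
}

#' Plant the IRES element into a background
#'
#' The element is substituted (not inserted) at each chosen site, so the
#' variable region keeps its 164nt length.
#'
#' @param background an `ires_background`.
#' @param placement integer vector of site indices (1-based into
#'   `background$site_starts`); empty leaves the background unchanged.
#' @param element element sequence (default the TEV IRES element UACUCCC).
#' @return the 164nt variable-region string.
#' @export
plant_element <- function(background, placement, element = "UACUCCC") {
  stopifnot(inherits(background, "ires_background"),
            nchar(element) == background$element_len)
  s <- background$sequence
  for (site in placement) {
    a <- background$site_starts[site] + 1L # 1-based
    substr(s, a, a + nchar(element) - 1L) <- element
  }
  s
}

#' Generate a set of Hamming-separated barcodes
#'
#' Greedy rejection sampling of fixed-length barcodes such that every pair
#' differs in at least `min_dist` positions; candidates containing any
#' excluded subsequence (by default the TEV element, to avoid planting
#' spurious sites) are rejected.  Deterministic given `seed`.
#'
#' @param count number of barcodes.
#' @param length barcode length in nt (default 10).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @param seed RNG seed.
#' @param exclude character vector of forbidden subsequences.
#' @param max_tries rejection-sampling budget.
#' @return character vector of `count` barcodes.
#' @export
generate_barcodes <- function(count, length = 10, min_dist = 3, seed = 1,
                              exclude = "UACUCCC", max_tries = 1000 * count) {
  stopifnot(count >= 1, length >= min_dist)
  b <- c("A", "C", "G", "U")
  accepted <- matrix(NA_character_, nrow = length, ncol = 0)
  with_seed(seed, {
    tries <- 0
    while (ncol(accepted) < count) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("barcode budget exhausted after accepting ", ncol(accepted),
             " of ", count)
      cand <- sample(b, length, replace = TRUE)
      cs <- paste(cand, collapse = "")
      if (any(vapply(exclude, grepl, logical(1), x = cs, fixed = TRUE)))
        next
      if (ncol(accepted) > 0 &&
          any(colSums(accepted != cand) < min_dist))
        next
      accepted <- cbind(accepted, cand)
    }
  })
  apply(accepted, 2, paste, collapse = "")
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' @param barcodes character vector of equal-length barcodes.
#' @return the smallest Hamming distance over all pairs.
#' @export
min_pairwise_hamming <- function(barcodes) {
  stopifnot(length(barcodes) >= 2)
  m <- do.call(cbind, strsplit(barcodes, ""))
  best <- nchar(barcodes[1])
  for (j in seq_len(ncol(m) - 1)) {
    d <- colSums(m[, (j + 1):ncol(m), drop = FALSE] != m[, j])
    best <- min(best, d)
  }
  best
}

#' Build the full combinatorial TEV-element oligo design
#'
#' Plants the TEV IRES element in every subset of the 8 predefined sites of
#' each background (2^8 = 256 oligos per background, 512 in total,
#' including the 0-site controls) and prepends a unique 10nt barcode
#' (pairwise Hamming distance >= 3) plus constant primer sequences.
#'
#' @param backgrounds list of `ires_background`s (default
#'   [tev_backgrounds()]).
#' @param element element sequence (default UACUCCC).
#' @param seed RNG seed for barcode generation.
#' @param primer5,primer3 constant amplification primer sequences
#'   (placeholders by default; configuration inputs).
#' @param barcode_length,min_dist barcode settings.
#' @return an `ires_tev_design` data.frame: `id`, `background`, `mask`
#'   (placement bitmask), `n_sites`, `barcode`, `variable` (164nt),
#'   `oligo` (primer5 + barcode + variable + primer3).
#' @export
design_tev_library <- function(backgrounds = tev_backgrounds(),
                               element = "UACUCCC", seed = 1,
                               primer5 = "GGCUAGCACG", primer3 = "CGUACGGAUC",
                               barcode_length = 10, min_dist = 3) {
  placements <- enumerate_placements(
    length(backgrounds[[1]]$site_starts))
  n_total <- length(placements) * length(backgrounds)
  barcodes <- generate_barcodes(n_total, barcode_length, min_dist, seed,
                                exclude = element)
  rows <- list()
  k <- 0
  for (bg in backgrounds) {
    for (pi in seq_along(placements)) {
      k <- k + 1
      pl <- placements[[pi]]
      rows[[k]] <- data.frame(
        id = sprintf("%s_%03d", bg$name, pi - 1),
        background = bg$name, mask = pi - 1L,
        n_sites = length(pl), barcode = barcodes[k],
        variable = plant_element(bg, pl, element),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$oligo <- paste0(as_rna(primer5), out$barcode, out$variable,
                      as_rna(primer3))
  class(out) <- c("ires_tev_design", "data.frame")
  attr(out, "element") <- element
  out
}

#' Write a design as FASTA plus TSV manifest
#'
#' @param design an `ires_tev_design`.
#' @param fasta_path output FASTA of full oligos.
#' @param manifest_path output TSV manifest.
#' @return `manifest_path`, invisibly.
#' @export
write_design <- function(design, fasta_path, manifest_path) {
  rs <- Biostrings::RNAStringSet(design$oligo)
  names(rs) <- design$id
  Biostrings::writeXStringSet(rs, fasta_path)
  utils::write.table(
    design[c("id", "background", "mask", "n_sites", "barcode")],
    manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest_path)
}

#' Simulate bicistronic measurements of a TEV design
#'
#' A simple per-site additive model: each planted element adds
#' `effect_per_site` activity units on top of `baseline`, with i.i.d.
#' Gaussian noise, measured in `n_replicates` independent replicates.
#'
#' @param design an `ires_tev_design`.
#' @param effect_per_site activity gain per planted element.
#' @param baseline background activity.
#' @param noise_sd measurement noise sd.
#' @param n_replicates biological replicates (default 2).
#' @param seed RNG seed.
#' @return data.frame with `id`, `background`, `n_sites`, `replicate`,
#'   `activity`.
#' @export
simulate_tev_measurements <- function(design, effect_per_site = 0.5,
                                      baseline = 0.2, noise_sd = 0.3,
                                      n_replicates = 2, seed = 1) {
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(rep)
      data.frame(id = design$id, background = design$background,
                 n_sites = design$n_sites, replicate = rep,
                 stringsAsFactors = FALSE)))
    out$activity <- baseline + effect_per_site * out$n_sites +
      stats::rnorm(nrow(out), 0, noise_sd)
    out
  })
}

#' Binned activity analysis of the TEV design
#'
#' Oligos are binned by number of planted sites (0-1, 2-3, 4-5, 6-8);
#' replicates enter the analysis as separate observations.  Per bin, the
#' fraction of observations with activity above the detection threshold
#' and summary statistics of the positive activities are reported; a
#' one-way ANOVA across bins is run on the activities of the positive
#' observations (skipped with a warning when any occupied bin has fewer
#' than 2 positive observations or fewer than 2 bins have positives).
#'
#' @param measurements data.frame with `n_sites` and `activity` (plus
#'   optional `id`, `replicate`).
#' @param threshold detection floor in activity units.
#' @return an `ires_binned_analysis` list: `table` (per-bin summary),
#'   `anova_F`, `anova_p`.
#' @export
binned_analysis <- function(measurements, threshold) {
  stopifnot(all(c("n_sites", "activity") %in% names(measurements)),
            all(measurements$n_sites >= 0), all(measurements$n_sites <= 8))
  bins <- cut(measurements$n_sites, breaks = c(-1, 1, 3, 5, 8),
              labels = c("0-1", "2-3", "4-5", "6-8"))
  pos <- measurements$activity > threshold
  tab <- do.call(rbind, lapply(levels(bins), function(b) {
    sel <- bins == b
    act <- measurements$activity[sel & pos]
    data.frame(bin = b, n_obs = sum(sel), n_positive = sum(sel & pos),
               fraction_positive = if (sum(sel) > 0) mean(pos[sel]) else NA,
               mean_positive_activity = if (length(act)) mean(act) else NA,
               median_positive_activity = if (length(act)) median(act) else NA)
  }))
  anova_F <- anova_p <- NA_real_
  occupied <- tab$n_positive > 0
  if (sum(occupied) < 2 || any(tab$n_positive[occupied] < 2)) {
    warning("ANOVA skipped: too few positive observations per bin")
  } else {
    fit <- stats::lm(activity ~ bin,
                     data = data.frame(activity = measurements$activity[pos],
                                       bin = droplevels(bins[pos])))
    an <- stats::anova(fit)
    anova_F <- an[["F value"]][1]
    anova_p <- an[["Pr(>F)"]][1]
  }
  structure(list(table = tab, anova_F = anova_F, anova_p = anova_p),
            class = "ires_binned_analysis")
}

#' @export
print.ires_binned_analysis <- function(x, ...) {
  print(x$table)
  cat(sprintf("one-way ANOVA on positive activities: F = %.3f, p = %.3g\n",
              x$anova_F, x$anova_p))
  invisible(x)
}
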