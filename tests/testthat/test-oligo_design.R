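test_that("placement enumeration covers all subsets", {
  expect_length(enumerate_placements(8), 256)
  expect_length(enumerate_placements(2), 4)
  sizes <- lengths(enumerate_placements(8))
  expect_equal(sum(sizes >= 6), 37)        # C(8,6)+C(8,7)+C(8,8)
  expect_equal(as.integer(table(cut(sizes, c(-1, 1, 3, 5, 8)))),
               c(9, 84, 126, 37))          # the analysis bins
  expect_equal(sizes[1], 0)                # empty placement included
})

test_that("element planting substitutes without changing length", {
  bgs <- tev_backgrounds()
  for (bg in bgs) {
    expect_equal(nchar(bg$sequence), 164)
    expect_equal(plant_element(bg, integer(0)), bg$sequence) # identity
    full <- plant_element(bg, 1:8)
    expect_equal(nchar(full), 164)
    for (s in bg$site_starts)
      expect_equal(substr(full, s + 1, s + 7), "UACUCCC")
    # an unplanted site keeps the background
    half <- plant_element(bg, c(1, 3, 5, 7))
    s2 <- bg$site_starts[2]
    expect_equal(substr(half, s2 + 1, s2 + 7),
                 substr(bg$sequence, s2 + 1, s2 + 7))
  }
  expect_error(design_background("x", strrep("A", 164),
                                 site_starts = c(0, 3)), "overlap")
})

test_that("barcode generation respects distance, exclusion and seed", {
  bc <- generate_barcodes(40, length = 10, min_dist = 3, seed = 4)
  expect_length(unique(bc), 40)
  expect_gte(min_pairwise_hamming(bc), 3)
  expect_false(any(grepl("UACUCCC", bc, fixed = TRUE)))
  expect_identical(bc, generate_barcodes(40, 10, 3, seed = 4))
  expect_false(identical(bc, generate_barcodes(40, 10, 3, seed = 5)))
  # impossible requests fail loudly
  expect_error(generate_barcodes(100, length = 3, min_dist = 3,
                                 max_tries = 500), "budget")
  # reference distances
  expect_equal(hamming_distance("AAAAAAAAAA", "CCCAAAAAAA"), 3)
  expect_equal(hamming_distance("AAAAAAAAAA", "ACAAAAAAAA"), 1)
})

test_that("minimum pairwise Hamming matches the brute-force scan", {
  withr::local_seed(5)
  bc <- replicate(15, random_rna(8))
  brute <- min(apply(combn(15, 2), 2,
                     function(p) hamming_distance(bc[p[1]], bc[p[2]])))
  expect_equal(min_pairwise_hamming(bc), brute)
})

test_that("the full design has 512 distinct, well-formed oligos", {
  des <- design_tev_library(seed = 2)
  expect_equal(nrow(des), 512)
  expect_equal(as.integer(table(des$background)), c(256, 256))
  expect_true(all(nchar(des$variable) == 164))
  expect_length(unique(des$barcode), 512)
  expect_length(unique(des$id), 512)
  # site counts per oligo match the placement mask
  expect_equal(des$n_sites, vapply(des$mask, function(m)
    sum(bitwAnd(m, bitwShiftL(1, 0:7)) > 0), numeric(1)))
  # manifest + FASTA writer round-trips ids
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_design(des, fa, tsv)
  man <- read.delim(tsv)
  expect_equal(nrow(man), 512)
  expect_equal(as.character(man$id), des$id)
})

test_that("binned analysis recovers a per-site additive effect", {
  des <- design_tev_library(seed = 3)
  meas <- simulate_tev_measurements(des, effect_per_site = 0.5,
                                    baseline = 0.2, noise_sd = 0.3,
                                    n_replicates = 2, seed = 6)
  expect_equal(nrow(meas), 1024) # two replicates pooled as observations
  ba <- binned_analysis(meas, threshold = 1)
  expect_equal(as.character(ba$table$bin), c("0-1", "2-3", "4-5", "6-8"))
  expect_true(all(diff(ba$table$fraction_positive) >= 0))
  expect_lt(ba$anova_p, 0.01)
  expect_true(all(diff(ba$table$mean_positive_activity) >= 0))
})

test_that("binned ANOVA matches a textbook two-pass computation", {
  toy <- data.frame(
    n_sites = rep(c(0, 2, 4, 7), each = 4),
    activity = c(1.1, 1.3, 1.2, 1.4, 2.0, 2.2, 2.1, 2.3,
                 3.0, 3.1, 3.2, 2.9, 4.0, 4.2, 4.1, 3.9))
  ba <- binned_analysis(toy, threshold = 0)
  g <- rep(1:4, each = 4)
  grand <- mean(toy$activity)
  ssb <- sum(tapply(toy$activity, g, function(v)
    length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(toy$activity, g, function(v) sum((v - mean(v))^2)))
  f_ref <- (ssb / 3) / (ssw / 12)
  expect_equal(ba$anova_F, f_ref, tolerance = 1e-12)
  expect_equal(ba$anova_p, pf(f_ref, 3, 12, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("degenerate measurements skip the ANOVA", {
  toy <- data.frame(n_sites = 0:8, activity = rep(0.1, 9))
  expect_warning(ba <- binned_analysis(toy, threshold = 1), "skipped")
  expect_true(all(ba$table$fraction_positive == 0))
  expect_true(is.na(ba$anova_F))
})
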