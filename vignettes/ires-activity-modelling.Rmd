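---
title: "Modelling IRES activity from RNA sequence k-mer features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling IRES activity from RNA sequence k-mer features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Internal Ribosome Entry Sites (IRESs) are RNA elements that recruit the
ribosome cap-independently.  Massively parallel bicistronic reporter assays
measure the IRES activity of tens of thousands of short RNA fragments at
once: a variable sequence is placed between two cistrons and downstream
reporter expression quantifies its ability to drive internal initiation.
Such libraries are dominated by inactive sequences — activity is
left-censored at an empty-vector detection floor, with roughly one sequence
in nine rising above it — and mix sequences of very different origins
(human 5'/3' UTRs and CDSs; positive- and negative-sense ssRNA, dsRNA and
retroviral genomes), which plausibly use different initiation mechanisms.

`irespred` models such data end to end: it represents each RNA by k-mer
features, screens them for association with activity under FDR control,
fits stochastic gradient-boosted regression tree ensembles inside a
double-loop cross-validation, and interprets the trained fold models to
produce signed, position-resolved sequence effects.  A synthetic-library
generator with exported ground truth makes every stage testable without any
external download.

## Sequence representation

Sequences are validated RNA strings (`ires_library()`), each carrying an
`aug_offset`: the number of bases 5' of the reporter start AUG.  All
positions are reported AUG-relative (0-based, half-open; negative =
upstream), so `[-20, 0)` is the 20nt immediately upstream of the AUG.

`build_matrix()` records, for every k-mer of length 1..`k_max` (cumulative
lengths; the interpreted models mix k = 1..4 features):

* **global counts** — overlapping occurrence counts over the whole
  sequence;
* **positional counts** — occurrences fully contained in 20nt windows that
  start at the AUG and advance 5'-ward in 10nt steps (10nt overlap).
  Windows are labelled by AUG-relative coordinates, so sequences of
  different lengths share columns; a partial 5' window is dropped and a
  sequence lacking a window contributes 0 there.  A 174nt sequence anchored
  at its 3' end therefore has 16 windows and, at `k_max = 4`,
  340 + 16 × 340 = 5780 features.

The `presence` representation caps all counts at 1.  Counting is
strand-specific and exact (a compiled counter, verified cell-by-cell
against a naive scanner in the test suite); matrices are stored sparse.

Whether the assay's positional effects should be measured from the
sequence 5' end or from the AUG was genuinely open; we anchor at the AUG
because all positional conclusions are expressed relative to the start
codon, and because it keeps window labels comparable across sequences of
unequal length.

## Feature screening

On each training partition (`preselect()`), every feature is associated
with activity: Spearman rank correlation for counts, two-sided
Mann-Whitney U for presence features (activity with vs without the
k-mer).  P-values are adjusted by Benjamini-Hochberg across all candidate
features jointly — the most conservative single-family choice — and a
feature is kept only if its FDR-adjusted q ≤ 0.05 **and** it is non-zero in
at least 10% of the partition's sequences.  Screening is recomputed on
every partition it serves (each inner training set during tuning, each
outer training set for the fold model), so held-out data never leak into
selection.

With heavy ties (censored activity, small counts) the Spearman p-value
uses the t approximation and the Mann-Whitney p-value the normal
approximation with tie and continuity corrections, matching
`stats::cor.test()` / `stats::wilcox.test()` exactly on the same data.
Zero-variance features get p = 1 and an undefined statistic.

## Model and tuning

`train_ensemble()` fits least-squares stochastic gradient boosting: 1000
trees by default, each fit to the gradient of the residual error on a
random fraction `f` of the training samples with learning rate `r`; trees
grow to arbitrary depth with complexity controlled by `m`, the minimum
training samples per leaf; every split draws `floor(sqrt(M'))` of the M'
pre-selected features.  The backend is xgboost configured to this
contract (histogram trees, loss-guided growth, unbounded depth,
`colsample_bynode`); the contract, not the backend, is what the tests pin
down.  Training matrices are densified: a zero count is an observed value,
and sparse inputs would route zeros down a default split direction as if
missing.

`(m, r, f)` are chosen per outer fold by a double-loop stratified 10-fold
cross-validation (`double_loop_cv()`): the outer training set is split into
10 inner folds; every grid cell is trained on each inner training set and
scored by R² on the inner validation set; the cell with the best mean
inner R² (ties: smaller `r`, then larger `m`, then declaration order) is
refit on the full outer training set and evaluated on the held-out outer
fold.  Folds are stratified so active and inactive sequences are balanced
to within one per fold.  The default grid spans the standard operating
range of the learner — `m ∈ {15, 30, 60}`, `r ∈ {0.01, 0.05, 0.1}`,
`f ∈ {0.5, 0.8}` — and is fully configurable.  One master seed derives all
fold and model seeds through a documented splitter (`derive_seed()`), so
the whole procedure is reproducible.

Performance is reported (`pooled_test_metrics()`) on predictions pooled
over the outer test folds with five metrics: R², Pearson r, Spearman ρ,
and — for separating active from inactive sequences — AUC-ROC (rank
formulation, ties mid-ranked) and AUC-PR (step integration over distinct
thresholds, no optimistic interpolation).  `group_division_test()`
supports the origin-group division by permuting group labels and comparing
the dispersion (variance, optionally range) of per-group R² against the
observed one; `incidence_subsample_curve()` quantifies how predictive
power depends on the number of active sequences in the training set.

## Interpretation

For each fold model, per-feature total variance-reduction importances are
normalized by the fold's maximum, making models with different feature
counts comparable; `aggregate_importances()` averages them across folds and
counts in how many folds each feature survived screening.  A feature is
**robust** if selected in every fold and **predictive** if its mean
normalized importance is at least 0.1 (`feature_effects()`).

Directionality comes from partial dependence: for each observed feature
value v, the expected prediction is approximated by substituting v into
the feature's column for all training rows and averaging fold predictions
(`partial_dependence()`, identical by construction to the brute-force
substitution oracle).  A feature is positive when the average
finite-difference slope of its curve is positive, otherwise negative —
flat and single-valued curves deliberately fall to the negative class.
The signed effect is the mean normalized importance carrying that sign.

Cross-group structure: `common_and_unique()` separates features selected
in ≥ 2 groups from group-specific ones (feature identity = k-mer + scope +
window); `find_islands()` reports maximal runs of ≥ 2 adjacent robust
windows (adjacent = start labels 10nt apart); `consensus_effects()` gives,
per window, the largest effect supported by ≥ 2 sign-agreeing groups (if
both signs ever qualified, the larger magnitude wins — a tie-break the
data rarely exercises); `gc_content_compare()` contrasts per-sequence GC
fractions between groups with a two-sided Wilcoxon rank-sum test.

## The TEV oligo design

`design_tev_library()` rebuilds the combinatorial dose-response design for
the 7nt C/U-rich TEV IRES element `UACUCCC`: the element is substituted
(length-preserving) into every subset of 8 predefined sites — all 2^8 =
256 placements per background, including the 0-site control — on two
164nt IRES-inactive backgrounds, 512 oligos in total.  Each oligo gets a
unique 10nt barcode; barcodes are drawn by seeded rejection sampling so
that every pair differs in ≥ 3 positions and none contains the element
itself.  Site coordinates default to 8 evenly spaced starts
(2, 22, ..., 142); they and the primer sequences are configuration
inputs.  The shipped native-like background is a synthetic placeholder
with HBB-like composition (the authentic beta-globin fragment is not
redistributed); the synthetic background is the inert 9nt spacer unit
concatenated and truncated to 164nt.

`binned_analysis()` bins oligos by site count (0-1, 2-3, 4-5, 6-8), pools
biological replicates as separate observations, and reports per-bin
fractions of active oligos, activity summaries of the active ones, and a
one-way ANOVA across bins on the active observations (skipped with a
warning when a bin has fewer than two active observations).

## The synthetic-data generator

`generate_library()` emulates the statistical structure the analysis
assumes, not the biology of any particular library:

* 174nt i.i.d. background sequences (GC 0.5) whose 3' end abuts the AUG;
* per-group motif recipes — every group plants `UUUU` (+1.0 activity
  units per occurrence, Gaussian positional profile centred at −50,
  s.d. 20nt) and `AAAA` (−0.8, global); the retroviral group adds `CCCC`
  (+1.0 at −200, s.d. 25nt), echoing the C-rich/retro contrast as
  *recoverable structure*, not asserted biology.  Motifs arise by chance
  and are additionally planted with probability 0.35 per sequence at a
  position drawn from the positional profile;
* latent activity = baseline (0) + Σ weighted motif effects + N(0, 0.25);
* the detection floor is the 0.89 quantile of the latent activities and
  observed activity is `max(latent, floor)` — left-censoring that yields
  ≈ 11% active sequences and the long right tail of the real assay.

Free parameters (baseline, noise s.d., GC, plant probability, equal group
weights) were fixed once at values a reporter-assay modeller would call
realistic — noise clearly smaller than a planted single-occurrence effect
but large enough that single sequences are unreliable — and are exposed in
`synthetic_config()`.  Ground truth (latent activities, planted positions)
is exported, and regeneration under a fixed seed is bit-identical.

What passing recovery tests show: that the pipeline finds planted
monotone, position-localised effects under censoring at realistic
signal-to-noise.  What they cannot show: performance on real libraries,
where effects are weaker, correlated with composition and confounded by
structure — the i.i.d. background has none of the phylogenetic or
compositional covariance of genomic fragments, and replicate noise is
i.i.d. Gaussian rather than assay-structured.

## Numerical choices and scaled problem sizes

* Ties: AUC-ROC mid-ranks; AUC-PR groups tied scores into one threshold
  block; grid-cell ties break deterministically (above).
* Degenerate inputs: constant features p = 1; constant activity refuses
  R²; empty post-screening matrices refuse training; single-class test
  folds report `NA` AUCs; all-equal latent activities are an error.
* The package's own validation runs at deliberately scaled settings so a
  full check remains a coffee-break computation: recovery replicates use
  n = 2000 sequences, 200 trees, a 2×2×1 grid and 5×5 CV (ten seeded
  replicates); the permutation and subsampling helpers accept an
  injectable fit function for the same reason.  Full-scale defaults
  (1000 trees, 10×10 CV, 3×3×2 grid) are what `run_ires_pipeline()` uses
  unless told otherwise.

## Limitations

* RNA secondary-structure features are out of scope by design.
* Activity units are assay-specific; only unitless metrics transfer.
* The average-derivative directionality is a summary of near-monotone
  partial dependence curves; strongly non-monotone effects would be
  misrepresented (inspect `partial_dependence()` curves directly in
  doubt).
* Reported R² on heavily censored data is dominated by the extremes;
  Spearman ρ is the more honest ranking metric there.
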