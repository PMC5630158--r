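# irespred

Predicting Internal Ribosome Entry Site (IRES) activity from RNA sequence.

Massively parallel bicistronic reporter assays measure, for tens of
thousands of short RNA fragments, how well each drives cap-independent
translation.  `irespred` is an R package for the computational side of such
experiments:

* represent each RNA as **global and position-aware k-mer features**
  anchored at the reporter start AUG (overlapping counts, or presence, for
  all k-mers of length 1..k; 20nt windows stepped 10nt 5'-ward of the AUG);
* **screen** features by association with activity — Spearman rank
  correlation for counts, Mann-Whitney U for presence — keeping those
  significant at Benjamini-Hochberg FDR 0.05 and present in ≥ 10% of the
  training sequences;
* fit **stochastic gradient-boosted regression tree ensembles**
  (least-squares boosting; learning rate *r*, per-tree subsample *f*,
  minimum leaf size *m*, √M′ features per split) with *(m, r, f)* tuned by
  a **double-loop 10-fold cross-validation** whose folds balance active and
  inactive sequences;
* evaluate with pooled test-set **R², Pearson r, Spearman ρ, AUC-ROC and
  AUC-PR**, plus a group-label permutation test and a positive-incidence
  subsampling curve;
* **interpret** the fold models: max-normalized importances, partial
  dependence and its average derivative for directionality, robust
  (selected in all folds) and predictive (mean normalized importance ≥ 0.1)
  signed effects, positional effect *islands*, cross-group consensus
  effects and GC-content contrasts;
* rebuild the **combinatorial TEV-element oligo design** — the 7nt element
  `UACUCCC` substituted into every subset of 8 sites on two 164nt
  backgrounds (512 oligos, Hamming-separated 10nt barcodes) — and run its
  binned dose-response analysis (bins 0-1/2-3/4-5/6-8 sites, fraction
  active, one-way ANOVA);
* generate **synthetic libraries with exported ground truth** (planted
  positional motifs, Gaussian noise, left-censoring at a detection floor
  giving ≈ 11% active sequences) so the whole pipeline is testable offline.

## Worked example

```r
library(irespred)

# a synthetic library: 174nt sequences, planted UUUU (+, strongest ~50nt
# upstream of the AUG) and AAAA (-), censored so ~11% are active
lib <- generate_library(synthetic_config(n = 1000, seed = 42))
mean(lib$records$active)   # 0.11

fit <- run_ires_pipeline(lib$records,
                         grid = hyperparameter_grid(m = c(15, 30), r = 0.1, f = 0.8),
                         n_folds = 5, n_inner = 5, n_trees = 200, seed = 42)
print(fit)
```

```
ires_analysis: n = 1000 (110 active)
pooled test: R2 = 0.482, r = 0.694, rho = 0.456, AUC-ROC = 0.917, AUC-PR = 0.734
22 robust & predictive feature(s)
             name folds_selected mean_norm_importance direction signed_effect
8     UUUU|global              5            0.9969858  positive     0.9969858
6      UUU|global              5            0.6272993  positive     0.6272993
17  UUU|[-60,-40)              5            0.4392577  positive     0.4392577
14 UUUU|[-50,-30)              5            0.3773571  positive     0.3773571
4       UU|global              5            0.3576185  positive     0.3576185
...
```

Reading the output: the model explains 48% of held-out activity variance
and separates active from inactive sequences (AUC-ROC 0.92).  The planted
U-rich motif is recovered as the strongest positive feature, both globally
and in the windows around −50 (AUG-relative nt), and the planted A-rich
motif appears with a negative signed effect (`AAA|global`, −0.17) —
exactly the planted structure.  `partial_dependence(fit$cv, "UUUU|global")`
shows the monotone curve behind the `positive` call.

The designed-oligo arm:

```r
design <- design_tev_library(seed = 1)          # 512 oligos, 2 backgrounds
meas   <- simulate_tev_measurements(design, seed = 1)
binned_analysis(meas, threshold = 1)            # fraction active rises with
                                                # site count; one-way ANOVA
```

## Package layout

* `R/dataset_io.R` — library container, TSV/FASTA I/O, group partition
* `R/kmer_features.R`, `src/kmer_count.cpp` — feature matrices
* `R/preselection.R`, `src/assoc.cpp` — association screening, BH FDR
* `R/training.R` — boosting contract, stratified folds, double-loop CV
* `R/evaluation.R` — metrics, permutation support, subsampling curve
* `R/interpretation.R` — importances, partial dependence, effects,
  islands, consensus
* `R/oligo_design.R` — TEV design, barcodes, binned analysis
* `R/synthetic_data.R` — ground-truth library generator
* `vignettes/ires-activity-modelling.Rmd` — the methods vignette
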