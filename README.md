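# angiopep

Sequence-based classification of anti-angiogenic peptides (AAPs).

Angiogenesis — the growth of new blood vessels — is essential for tumor
proliferation and metastasis, and peptides that inhibit it are candidate
cancer therapeutics. Screening peptides experimentally is expensive, so
sequence-based classifiers are used to rank candidates before the bench.
`angiopep` provides the full model-building pipeline for this problem as a
tidyverse-native R package:

* **Featurization** — every peptide is encoded as a vector of **4335 numeric
  values from 58 descriptor types**: compositional descriptors (AAC, DPC,
  GAAC/GDPC, CKSAAP/CKSAAGP, CTriad, DDE), sequence-order descriptors
  (APAAC/PAAC, Shannon entropies, residue distance distributions, CTD), and
  physicochemical scale profiles (Ez membrane-insertion potential, Z3/Z5
  z-scales, composite and binary-property scales, 36 AAindex
  autocorrelation descriptors).
* **Robust normalization** — per-feature quartile scaling
  `y = (x − Median(X)) / (Q3(X) − Q1(X))`, fitted on training data only.
* **Feature selection** — a shadow-feature (Boruta-style) random-forest
  ranking followed by a heuristic top-N subset search: for
  N = 50, 60, …, 200, the top-N prefix is scored by stratified 5-fold CV
  with six classifier families; per N the best MCC is kept
  (`Best_MCC_N = max_i MCC_N^i`) and the selected subset is the prefix
  maximizing it, smallest N on ties.
* **Models and tuning** — SVM (RBF), LDA, random forest, extremely
  randomized trees, gradient-boosted trees and elastic-net logistic
  regression, tuned by a tree-structured Parzen estimator against 10-fold
  CV MCC with median-rule pruning.
* **Evaluation** — accuracy, precision, recall, specificity, MCC
  (`MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))`), rank-based
  AUC, repeated stratified CV, the retrain-then-independent-test protocol,
  plus probability-bin TPR and residue-property-stratified accuracy
  analyses.
* **Synthetic data** — a generator of labeled peptide sets with class-biased
  residue composition (C/P/R/S/W enriched in positives, A/E/I/L/V in
  negatives) and of feature matrices with planted informative columns, so
  every stage is testable end to end with known ground truth.

See `vignettes/angiopep-methods.Rmd` for the modeling choices and their
rationale.

## Worked example

```r
library(angiopep)

# Synthetic N-terminal dataset: 60 + 60 peptides of length 15, positive
# class enriched in C/P/R/S/W, negative in A/E/I/L/V.
ds <- generate_peptide_dataset(
  synth_profile("nterm15", n_pos = 60, n_neg = 60, enrichment = 5, seed = 7)
)

# Encode with the default 58-type registry, then rank and select features.
fm     <- encode_peptides(ds)                      # 120 x 4335 features
scaled <- scale_features(fm, fit_quartile_scaler(fm))
rank   <- shadow_feature_ranking(scaled, n_iter = 15, seed = 7)
search <- heuristic_subset_search(fm, rank, grid = seq(50, 200, by = 50),
                                  repeats = 1, seed = 7)
glance(search)
#> # A tibble: 1 x 4
#>   n_selected best_mcc best_family grid_sizes
#>        <int>    <dbl> <chr>            <int>
#> 1         50        1 svm                  4

# Tune the winning family on the selected subset and cross-validate.
sub  <- fm[, c("sample_id", "label", search$features)]
tune <- tune_hyperparameters(sub, "svm", n_trials = 10, seed = 7)
cv   <- cross_validate(sub, spec_from_tuning(tune), k = 10, repeats = 2,
                       seed = 7)
glance(cv)
#> # A tibble: 1 x 10
#>     acc   pre   rec    sp   mcc   auc    tp    tn    fp    fn
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <int> <int> <int> <int>
#> 1     1     1     1     1     1     1   120   120     0     0
```

The selected 50-feature subset separates the two synthetic classes
perfectly (pooled repeated 10-fold CV MCC 1.0): the enrichment signal
planted by the generator is strong, and the pipeline recovers it. `autoplot()`
methods visualize the subset-search grid, tuning trajectory, probability-bin
TPR and property-stratified accuracy; `tidy()`/`glance()` return all results
as tibbles.

A thin command-line interface over the same functions ships at
`inst/cli/angiopep.R` (subcommands `simulate`, `encode`, `normalize`,
`select`, `tune`, `train`, `eval`, `analyze`).

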