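---
title: "Methods: sequence-based anti-angiogenic peptide classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based anti-angiogenic peptide classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Anti-angiogenic peptides (AAPs) inhibit the formation of new blood vessels
and are candidate anti-cancer therapeutics. Experimentally screening peptides
is slow, so sequence-based classifiers that score a peptide's probability of
anti-angiogenic activity are used to prioritize candidates. `angiopep`
implements such a classifier as a pipeline of testable stages: comprehensive
featurization, robust normalization, shadow-feature ranking, a heuristic
subset search, model tuning, and a benchmarking protocol, plus a synthetic
data generator so every stage can be exercised and validated without any
external dataset.

## The encoding envelope

Each peptide is mapped to a vector of **4335 numeric values from 58
descriptor types**. The complete composition of such envelopes is rarely
printed in full anywhere; this package's registry is reconstructed from the
descriptor families that the field's feature calculators (iFeature-style
tools and physicochemical scale libraries) provide, under hard constraints:
exactly 58 types, exactly 4335 values, and fixed sizes for every named
family. The registry is:

| family | size | notes |
|---|---|---|
| length | 1 | sequence length |
| AAC / DPC | 20 / 400 | residue and dipeptide composition |
| GAAC / GDPC | 5 / 25 | 5-group composition (aliphatic GAVLMI, aromatic FYW, positive KRH, negative DE, uncharged STCPNQ) |
| CKSAAP | 1200 | k-spaced residue pairs, gaps 0..2 |
| CKSAAGP | 150 | k-spaced group pairs, gaps 0..5 (25 pairs x 6 gaps) |
| APAAC / PAAC | 30 / 25 | Chou's pseudo amino-acid compositions, lambda = 5, w = 0.05 |
| SEP / SER | 1 / 20 | Shannon entropy of the composition and its per-residue terms |
| DDE | 400 | dipeptide deviation from codon-usage expectation |
| CTriad | 343 | conjoint triads over 7 residue classes |
| CTDC / CTDT / CTDD | 39 / 39 / 195 | 13-property, 3-group composition / transition / distribution |
| DDR | 20 | mean normalized gap between repeated residues |
| Ez | 30 | membrane-insertion pseudo-energy (3 parameters x lags 1..10) |
| Z3 / Z5 | 30 / 75 | z-scales, 3 dims x lags 1..10 and 5 dims x lags 1..15 |
| Cougar | 30 | composite scale (hydropathy, charge, volume) x lags 1..10 |
| ABHPRK | 105 | 7 binary property axes x lags 1..15 |
| AAindex autocorrelation | 36 x 32 | per property: mean, sd, Moreau-Broto/Moran/Geary at lags 1..10 |

Design notes, in the order the decisions came up:

* **CKSAAP gap range.** The family's size is a free parameter; gaps 0..2
  (1200 values) keep every block computable for 15-mer N-terminal data and
  make the totals close exactly.
* **Multi-dimensional scales.** Each scale table is z-standardized per
  dimension over the 20 residues and aggregated by lagged autocovariance.
  The lag ranges are pinned per scale so the sizes land on the fixed values
  (e.g. 5 x 15 = 75 for Z5, 7 x 15 = 105 for ABHPRK).
* **AAindex descriptors.** The 36 single-property descriptors use well-known
  complete AAindex entries (hydrophobicity, volume, polarity, flexibility,
  secondary-structure propensities, ...) loaded at run time from the aaindex
  tables bundled with `seqinr`. Each contributes 32 values: profile mean and
  SD plus three standard autocorrelation statistics at lags 1..10.
* **DDR statistic.** The literature leaves the exact "distance distribution"
  summary open; we pin the mean gap between consecutive occurrences of a
  residue, normalized by length, with sentinel 0 for absent/singleton
  residues.
* **Short sequences.** Any lag/gap term that cannot be computed is set to 0
  with a collected warning, never an error: N-terminal 15-mers must flow
  through the full envelope.
* **Cougar.** Treated as a single 30-value composite spec (hydropathy,
  net side-chain charge, side-chain volume) rather than a bundle of other
  scales; the registry manifest records the exact layout.

`encode_peptides()` enforces that every spec emits exactly its declared size
with stable names (`"<TYPE>.<feature>"` — the join key for selection and
reporting), and stamps the matrix with a registry hash.

## Normalization

Features are scaled robustly: \(y = (x - \mathrm{Median}(X)) / (Q3(X) -
Q1(X))\), fitted on training data only, giving every non-degenerate feature
median 0 and IQR 1 on the training matrix. Quantiles use the
linear-interpolation convention (R type 7), the common default; the
convention matters for small n and is recorded here so numbers are
comparable. Zero-IQR features are centered only (divisor 1) instead of
dropped, keeping the 4335-column layout stable. Inside every
cross-validation fold the scaler is re-fitted on the training fold only;
this is leakage-safe, and slightly more conservative than fitting once on
the full development set.

## Feature selection

**Ranking.** A shadow-feature procedure: each iteration appends a permuted
copy of every feature, fits a random forest (impurity importance), and
counts a "hit" for every real feature whose importance beats the best
shadow. Hits over `n_iter` iterations (default 30) are tested against a
Binomial(n_iter, 1/2) null with a two-sided test at alpha = 0.01: features
with significantly more hits are *confirmed*, significantly fewer
*rejected*, the rest *tentative*. The final ranking orders confirmed before
tentative before rejected, by mean importance, ties broken by name — a
strict, deterministic order over **all** features, so top-N prefixes are
always defined (rejected features may enter very large prefixes by design).

**Subset search.** For candidate sizes N = 50..200 in steps of 10 (16
sizes), the top-N prefix is scored by stratified 5-fold cross-validation
with each of the six classifier families at default hyperparameters;
"iterative" CV is interpreted as R repeats with distinct fold seeds
(default R = 3) whose MCCs are averaged. Per N the best family MCC is kept;
the selected subset is the prefix maximizing that best MCC, **smallest N on
ties** (parsimony), with family ties reported in the fixed precedence order
SVM, LDA, RF, ET, GBT, elastic net.

## Models

Six families, all emitting class-1 probabilities (hard labels at the 0.5
threshold; the datasets this pipeline targets are balanced by construction,
so no reweighting is applied):

* SVM with RBF kernel (`e1071`), defaults cost 1, gamma 1/p;
* LDA (`MASS`);
* random forest (`ranger`, 500 trees);
* extremely randomized trees (`ranger` with `extratrees` splitting, no
  bootstrap);
* gradient-boosted trees (`xgboost`, 200 rounds, learning rate 0.1);
* elastic-net logistic regression (`glmnet`, alpha 0.5, lambda 0.01).

**Tuning.** `tune_hyperparameters()` maximizes mean stratified-CV MCC with
a tree-structured Parzen estimator: after 10 random startup trials,
completed trials are split into good/bad sets at the top-25% quantile of
the score and each parameter's next value maximizes the ratio of Gaussian
kernel densities (with a uniform floor) between the good and bad sets,
log-transformed where the search space is log-scaled. A median rule prunes
trials whose running fold mean after 3 folds falls below the median of
previous trials at the same depth. Search spaces are declared per family in
`default_search_space()` (e.g. SVM cost 1e-2..1e3 and gamma 1e-4..1e1, both
log-uniform), not hidden in code. The whole trial log is deterministic
given the seed. The tuning objective is 10-fold CV MCC, matching the final
evaluation protocol.

## Evaluation protocol

Accuracy, precision, recall/sensitivity, specificity and MCC follow the
standard confusion-matrix definitions; metrics with an empty denominator
return a flagged sentinel 0 (balanced benchmark data never hits this).
AUC is the rank-based Mann-Whitney statistic with midranks for ties.
Cross-validation pools confusion counts over folds (and repeats) for the
threshold metrics and averages AUC over folds; both aggregations are
reported because conventions differ across papers. The independent test
retrains on the complete development set with the tuned hyperparameters
before scoring the held-out set once.

Two post-hoc analyses mirror common practice: `tpr_by_probability_bins()`
bins predictions by probability (default width 0.1) and reports per-bin
counts and the fraction of actual positives — well-behaved models show TPR
rising with probability; `accuracy_by_residue_property()` stratifies
accuracy by the peptide's ratio of hydrophobic (V, I, L, M, F, W, C),
hydrophilic (R, N, D, E, Q, H, K, S, T) or charged (E, D, R, K, H)
residues (default ratio bin 0.1). Bin widths are conventions, recorded in
the outputs.

## Synthetic data

`generate_peptide_dataset()` draws residues from class-specific
multinomials: a uniform base composition re-weighted by an enrichment
factor (default 5) on C, P, R, S, W for positives and A, E, I, L, V for
negatives — the residue propensities reported for curated AAP collections —
with lengths uniform on 10..50 (`"fulllength"`) or fixed at 15
(`"nterm15"`). Defaults (100 + 100 peptides) match the scale of the curated
datasets. The generator emulates compositional class structure only: no
sequence motifs, no secondary structure, no identity clustering, and a
uniform rather than proteome background. Passing tests therefore
demonstrate that the pipeline machinery recovers *compositional* signal; on
real data, where the signal is weaker and partly positional, absolute
performance will be lower even though every protocol step is identical.
`generate_feature_matrix()` plants a known number of informative columns
(class mean shift in SD units) among pure-noise columns and returns the
ground truth, which drives the selection-recovery tests.

## Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation); ties in ranking broken by
  feature name; all RNG from a single seeded stream per entry point.
* Zero-variance feature columns are dropped at model-fit time (LDA and
  glmnet cannot digest them) and ignored at prediction; the scaler itself
  never drops columns.
* Homopolymer profiles have zero variance: Moran/Geary autocorrelations and
  the profile SD return sentinel 0.
* Probability bins are left-closed with the top bin closed on both sides;
  empty bins carry `NA` TPR and are flagged rather than interpolated.
* Folds are stratified per class; a fold losing a class entirely is an
  error in tuning (trial marked failed) and a warning elsewhere.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at reduced
but representative sizes chosen as this package's own validation scale: the
selection-recovery experiment uses 200 samples with 10 informative among
500 features; the end-to-end run uses the `"nterm15"` profile (100 + 100
peptides, full 4335-value envelope), a 4-point subset grid (50..200 step
50), 15 ranking iterations, 10 TPE trials and repeated 10-fold CV. At these
settings the factor-5 classes are cleanly separable (CV MCC above 0.9), so
the checks validate machinery, not generalization.

## Known limitations

* The registry reconstructs a plausible 58-type envelope; other tools'
  envelopes with the same headline numbers may differ in the free
  parameters (CKSAAP gaps, APAAC lambda, the AAindex selection).
* The TPE implementation factorizes the search space per parameter (no
  parameter interactions in the proposal density), which is standard but
  can be slower to converge on strongly coupled spaces.
* LDA on p > n prefixes relies on collinearity warnings being suppressed;
  its posteriors remain usable but are not regularized.
* The synthetic generator's compositional bias makes selection easy; it is
  not evidence about feature relevance on real peptides.
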