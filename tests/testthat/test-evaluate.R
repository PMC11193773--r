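# Brute-force metric oracle, independent of compute_metrics().
oracle_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    acc = (tp + tn) / length(truth),
    pre = if (tp + fp > 0) tp / (tp + fp) else 0,
    rec = if (tp + fn > 0) tp / (tp + fn) else 0,
    sp  = if (tn + fp > 0) tn / (tn + fp) else 0,
    mcc = if (den > 0) (tp * tn - fp * fn) / den else 0
  )
}

# Brute-force AUC: fraction of positive-negative pairs ordered correctly,
# ties counted 1/2.
oracle_auc <- function(truth, prob) {
  pos <- prob[truth == 1]; neg <- prob[truth == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("metric formulas match hand-derived cases", {
  r <- compute_metrics(list(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(r$mcc, 0)
  expect_equal(r$acc, 0.5)

  perfect <- compute_metrics(list(tp = 10, tn = 12, fp = 0, fn = 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$pre, 1)

  r2 <- compute_metrics(list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(r2$mcc, 10 / sqrt(600), tolerance = 1e-12)
  expect_equal(r2$rec, 0.6)
  expect_equal(r2$sp, 0.8)

  expect_error(compute_metrics(list(tp = -1, tn = 1, fp = 0, fn = 0)),
               "negative")
  zero <- compute_metrics(list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_equal(zero$pre, 0)
  expect_true("pre" %in% attr(zero, "undefined"))
})

test_that("metrics agree exactly with a brute-force counter on random draws", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    truth <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    got <- compute_metrics(confusion_counts(truth, pred))
    want <- oracle_metrics(truth, pred)
    expect_identical(
      c(got$acc, got$pre, got$rec, got$sp, got$mcc),
      c(want$acc, want$pre, want$rec, want$sp, want$mcc)
    )
  }
})

test_that("MCC swap symmetry and recall/specificity label inversion hold", {
  set.seed(32)
  for (i in 1:50) {
    tp <- sample(0:20, 1); tn <- sample(0:20, 1)
    fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (tp + tn + fp + fn == 0) next
    a <- compute_metrics(list(tp = tp, tn = tn, fp = fp, fn = fn))
    b <- compute_metrics(list(tp = tn, tn = tp, fp = fn, fn = fp))
    expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
    expect_equal(a$rec, b$sp, tolerance = 1e-12)
  }
})

test_that("rank-based AUC equals brute-force pair ordering up to n = 50", {
  expect_equal(compute_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(compute_auc(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.8)), 0.75)
  set.seed(33)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    truth <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    prob <- round(stats::runif(n), 2)  # rounding forces ties
    expect_equal(compute_auc(truth, prob), oracle_auc(truth, prob),
                 tolerance = 1e-12)
  }
  expect_error(compute_auc(c(1, 1), c(0.5, 0.6)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  truth <- sample(0:1, 80, replace = TRUE)
  prob <- stats::runif(80)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                        direction = "<")))
  expect_equal(compute_auc(truth, prob), ref, tolerance = 1e-12)
})

test_that("cross-validation pools counts, is deterministic and solvable", {
  d <- separable_matrix(n = 40, margin = 6)
  spec <- make_default_model("svm")
  cv <- cross_validate(d, spec, k = 5, repeats = 2, seed = 9)
  counts <- attr(cv, "counts")
  expect_equal(counts$tp + counts$tn + counts$fp + counts$fn, 40L * 2L)
  expect_equal(cv$mcc, 1)
  cv2 <- cross_validate(d, spec, k = 5, repeats = 2, seed = 9)
  expect_equal(tibble::as_tibble(cv), tibble::as_tibble(cv2))
  # leave-one-out: n folds of size 1
  loo <- cross_validate(d[1:10, ], spec, k = 10, repeats = 1, seed = 1)
  expect_equal(nrow(attr(loo, "folds")), 10L)
  expect_true(all(attr(loo, "folds")$n == 1L))
})

test_that("independent test retrains on dev and evaluates once on test", {
  cfg <- generator_config(n_pos = 30, n_neg = 30, length_range = c(10, 20),
                          enrichment = 8, seed = 41)
  ds <- generate_peptide_dataset(cfg)
  sp <- stratified_split(ds, 0.8, seed = 42)
  reg <- registry_subset(default_registry(), c("AAC", "GAAC", "DPC"))
  spec <- make_default_model("enet")
  rep <- independent_test(sp$dev, sp$test, spec, reg)
  expect_true(rep$mcc > 0.5)
  preds <- attr(rep, "predictions")
  expect_equal(nrow(preds), nrow(sp$test))
  expect_true(all(preds$.prob >= 0 & preds$.prob <= 1))
  expect_equal(preds$.pred, as.integer(preds$.prob >= 0.5))
  # overlapping ids are rejected
  expect_error(independent_test(sp$dev, sp$dev, spec, reg), "share ids")
})

test_that("probability-bin report partitions samples and flags empty bins", {
  truth <- c(1, 1, 1, 0, 0)
  prob <- c(1.0, 0.95, 0.62, 0.61, 0.05)
  rep <- tpr_by_probability_bins(truth, prob, bin_width = 0.1)
  expect_equal(sum(rep$n), 5L)
  expect_equal(rep$tpr[rep$bin_lo == 0.9], 1)
  expect_equal(rep$tpr[rep$bin_lo == 0.6], 0.5)
  expect_true(is.na(rep$tpr[rep$bin_lo == 0.3]))
  expect_equal(nrow(rep), 10L)
})

test_that("residue property ratios use the declared sets", {
  expect_equal(residue_property_ratio("VILMFWC", "hydrophobic"), 1)
  expect_equal(residue_property_ratio("EDRKH", "charged"), 1)
  expect_equal(residue_property_ratio("EDRKH", "hydrophilic"), 1)
  expect_equal(residue_property_ratio("GGGG", "hydrophobic"), 0)
  expect_equal(residue_property_ratio("GGGG", "hydrophilic"), 0)
  expect_equal(residue_property_ratio("GGGG", "charged"), 0)
  expect_equal(residue_property_ratio("VVAA", "hydrophobic"), 0.5)
  expect_error(residue_property_ratio("AC", "greasy"), "unknown property")
})

test_that("property-stratified accuracy bins every peptide once", {
  ds <- tiny_dataset()
  preds <- tibble::tibble(sample_id = ds$id,
                          .pred = c(1L, 1L, 0L, 0L, 0L))
  rep <- accuracy_by_residue_property(ds, preds, "hydrophobic")
  expect_equal(sum(rep$n), nrow(ds))
  expect_true(all(rep$accuracy[rep$n > 0] >= 0 &
                    rep$accuracy[rep$n > 0] <= 1))
  short <- preds[1:3, ]
  expect_error(accuracy_by_residue_property(ds, short, "charged"),
               "cover")
})

test_that("composition propensity recovers designed class differences", {
  ds <- tibble::tibble(
    id = c("p1", "p2", "n1", "n2"),
    sequence = c("CCCC", "CCCC", "AAAA", "AAAA"),
    label = c(1L, 1L, 0L, 0L)
  )
  prop <- composition_propensity(ds)
  aac <- prop[prop$level == "AAC", ]
  expect_equal(aac$diff[aac$feature == "C"], 1)
  expect_equal(aac$diff[aac$feature == "A"], -1)
  # identical classes -> all differences zero
  same <- tibble::tibble(id = c("a", "b"), sequence = c("ACDE", "ACDE"),
                         label = c(1L, 0L))
  prop2 <- composition_propensity(same)
  expect_true(all(prop2$diff == 0))
  expect_error(composition_propensity(ds[1:2, ]), "both classes")
})
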