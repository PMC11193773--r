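# Confusion-based metrics, AUC, cross-validation and independent-test
# protocols, plus the post-hoc analyses (probability-binned true-positive
# rate, residue-property strata, class composition propensity).

#' Confusion counts from truth and predictions
#'
#' @param truth Integer/logical vector of true labels (1 = positive).
#' @param pred Integer/logical vector of predicted labels.
#' @return A `confusion_counts` list with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth); pred <- as.integer(pred)
  structure(list(
    tp = sum(truth == 1L & pred == 1L),
    tn = sum(truth == 0L & pred == 0L),
    fp = sum(truth == 0L & pred == 1L),
    fn = sum(truth == 1L & pred == 0L)
  ), class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy, precision, recall (sensitivity), specificity and the
#' Matthews correlation coefficient:
#' \deqn{MCC = (TP.TN - FP.FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' Metrics with an undefined denominator return the sentinel 0 and are named
#' in the `undefined` attribute.
#'
#' @param counts A `confusion_counts` object or a list/vector with `tp`,
#'   `tn`, `fp`, `fn`.
#' @return A one-row `eval_report` tibble with columns `acc`, `pre`, `rec`,
#'   `sp`, `mcc` (and `auc = NA`).
#' @examples
#' compute_metrics(list(tp = 3, fp = 1, tn = 4, fn = 2))$mcc  # 10/sqrt(600)
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  vals <- c(tp, tn, fp, fn)
  if (any(vals < 0)) stop("negative confusion counts", call. = FALSE)
  n <- tp + tn + fp + fn
  if (n < 1) stop("no samples evaluated", call. = FALSE)
  undefined <- character()
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  acc <- (tp + tn) / n
  pre <- safe(tp, tp + fp, "pre")
  rec <- safe(tp, tp + fn, "rec")
  sp  <- safe(tn, tn + fp, "sp")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { undefined <- c(undefined, "mcc"); 0 } else
    (tp * tn - fp * fn) / mcc_den
  out <- tibble::tibble(acc = acc, pre = pre, rec = rec, sp = sp,
                        mcc = mcc, auc = NA_real_)
  attr(out, "counts") <- list(tp = tp, tn = tn, fp = fp, fn = fn)
  attr(out, "undefined") <- undefined
  class(out) <- c("eval_report", class(out))
  out
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midranks for ties: the fraction of positive-negative pairs ordered
#' correctly, counting ties as 1/2.
#'
#' @param truth Binary truth labels (1 = positive); both classes required.
#' @param prob Numeric prediction scores/probabilities.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(truth, prob) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(prob, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

mcc_of <- function(counts) compute_metrics(counts)$mcc

# Stratified fold assignment: returns an integer fold id per row,
# deterministic given the RNG state.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    # cycle fold ids across classes so every fold is populated even when a
    # class has fewer members than there are folds (e.g. leave-one-out)
    folds[idx] <- ((seq_along(idx) + offset - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  if (any(vapply(split(labels, folds), function(l) length(unique(l)) < 2,
                 logical(1)))) {
    warning("some folds contain a single class", call. = FALSE)
  }
  folds
}

# One CV pass: fit scaler + model per training fold, predict the held-out
# fold. Returns tibble(row, fold, truth, prob, pred).
cv_predictions <- function(data, spec, k, fold_seed) {
  labels <- data$label
  set.seed(fold_seed)
  folds <- stratified_folds(labels, k)
  res <- lapply(seq_len(k), function(f) {
    tr <- data[folds != f, , drop = FALSE]
    te <- data[folds == f, , drop = FALSE]
    scaler <- fit_quartile_scaler(tr)
    model <- fit_model(scale_features(tr, scaler), spec)
    pr <- predict(model, scale_features(te, scaler))
    tibble::tibble(row = which(folds == f), fold = f,
                   truth = te$label, prob = pr$.prob, pred = pr$.pred)
  })
  dplyr::bind_rows(res)
}

#' Repeated stratified cross-validation of one model spec
#'
#' Runs `repeats` rounds of stratified `k`-fold cross-validation. Inside each
#' training fold the quartile scaler is re-fitted (no leakage from held-out
#' folds). Threshold metrics are computed from the confusion counts pooled
#' over all folds and repeats; AUC is averaged over folds.
#'
#' @param data Feature-matrix tibble with a `label` column.
#' @param spec A `model_spec` from [make_default_model()] or tuning.
#' @param k Number of folds (default 10).
#' @param repeats Number of CV repetitions with distinct fold seeds.
#' @param seed Integer seed; results are deterministic given it.
#' @return An `eval_report` tibble (one row) with a `folds` attribute holding
#'   the per-fold breakdown and a `predictions` attribute with per-sample
#'   out-of-fold predictions.
#' @export
cross_validate <- function(data, spec, k = 10, repeats = 1, seed = 1) {
  stopifnot(k >= 2)
  preds <- dplyr::bind_rows(lapply(seq_len(repeats), function(r) {
    dplyr::mutate(cv_predictions(data, spec, k, fold_seed = seed + 1000L * r),
                  repeat_id = r)
  }))
  report <- compute_metrics(confusion_counts(preds$truth, preds$pred))
  per_fold <- preds |>
    dplyr::group_by(.data$repeat_id, .data$fold) |>
    dplyr::summarise(
      n = dplyr::n(),
      mcc = mcc_of(confusion_counts(.data$truth, .data$pred)),
      auc = if (length(unique(.data$truth)) > 1)
        compute_auc(.data$truth, .data$prob) else NA_real_,
      .groups = "drop"
    )
  report$auc <- mean(per_fold$auc, na.rm = TRUE)
  attr(report, "folds") <- per_fold
  attr(report, "predictions") <- preds
  attr(report, "protocol") <- list(k = k, repeats = repeats, seed = seed)
  report
}

#' Independent test protocol
#'
#' Encodes development and test peptide sets with the same registry, fits the
#' scaler and the model on the full development set (the retrain-with-all-data
#' step that precedes an independent test), restricts to the selected
#' features, and evaluates once on the held-out test set.
#'
#' @param dev,test Labeled peptide tibbles (`id`, `sequence`, `label`),
#'   disjoint by id.
#' @param spec A `model_spec`.
#' @param registry Descriptor registry (default [default_registry()]).
#' @param features Optional character vector of selected feature names; all
#'   encoded features when `NULL`.
#' @return An `eval_report` with a `predictions` attribute (per test peptide).
#' @export
independent_test <- function(dev, test, spec, registry = default_registry(),
                             features = NULL) {
  overlap <- intersect(dev$id, test$id)
  if (length(overlap)) {
    stop("dev and test sets share ids: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  dev_m <- encode_peptides(dev, registry)
  test_m <- encode_peptides(test, registry)
  if (!is.null(features)) {
    missing <- setdiff(features, feature_names(dev_m))
    if (length(missing)) {
      stop("selected features absent from encoding: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    keep <- c("sample_id", "label", features)
    dev_m <- dev_m[, keep]
    test_m <- test_m[, keep]
  }
  scaler <- fit_quartile_scaler(dev_m)
  model <- fit_model(scale_features(dev_m, scaler), spec)
  pr <- predict(model, scale_features(test_m, scaler))
  report <- compute_metrics(confusion_counts(test_m$label, pr$.pred))
  report$auc <- if (length(unique(test_m$label)) > 1)
    compute_auc(test_m$label, pr$.prob) else NA_real_
  attr(report, "predictions") <- dplyr::bind_cols(
    tibble::tibble(sample_id = test_m$sample_id, truth = test_m$label), pr
  )
  report
}

#' True-positive rate by prediction-probability bins
#'
#' Bins predictions by probability and reports, per bin, the number of
#' sequences and the fraction that are actual positives (the bin-wise
#' true-positive rate). Empty bins are flagged with `tpr = NA`.
#'
#' @param truth Binary truth labels.
#' @param prob Predicted probabilities in `[0, 1]`.
#' @param bin_width Probability bin width (default 0.1).
#' @return A `prob_bin_report` tibble with columns `bin_lo`, `bin_hi`,
#'   `bin_mid`, `n`, `tpr`.
#' @export
tpr_by_probability_bins <- function(truth, prob, bin_width = 0.1) {
  stopifnot(all(prob >= 0 & prob <= 1))
  edges <- round(seq(0, 1, by = bin_width), 10)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin <- cut(prob, breaks = edges, include.lowest = TRUE, right = FALSE)
  # right = FALSE makes bins [lo, hi); fold prob == 1 into the top bin
  bin[prob == 1] <- levels(bin)[length(levels(bin))]
  out <- tibble::tibble(truth = as.integer(truth), bin = bin) |>
    dplyr::count(.data$bin, .drop = FALSE, name = "n") |>
    dplyr::mutate(
      bin_lo = edges[as.integer(.data$bin)],
      bin_hi = edges[as.integer(.data$bin) + 1L],
      bin_mid = (.data$bin_lo + .data$bin_hi) / 2
    )
  pos <- tibble::tibble(truth = as.integer(truth), bin = bin) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(npos = sum(.data$truth), .groups = "drop")
  out$tpr <- ifelse(out$n > 0, pos$npos / out$n, NA_real_)
  out <- out[, c("bin_lo", "bin_hi", "bin_mid", "n", "tpr")]
  class(out) <- c("prob_bin_report", class(out))
  out
}

#' Residue-property ratio of peptides
#'
#' Fraction of residues belonging to a property set: hydrophobic (V, I, L, M,
#' F, W, C), hydrophilic (R, N, D, E, Q, H, K, S, T) or charged (E, D, R, K,
#' H). The sets overlap by definition.
#'
#' @param sequence Character vector of peptide sequences.
#' @param property One of `"hydrophobic"`, `"hydrophilic"`, `"charged"`.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
residue_property_ratio <- function(sequence, property) {
  set <- PROPERTY_SETS[[property]]
  if (is.null(set)) {
    stop("unknown property: ", property, "; use one of ",
         paste(names(PROPERTY_SETS), collapse = ", "), call. = FALSE)
  }
  vapply(strsplit(sequence, ""), function(ch) mean(ch %in% set), numeric(1))
}

#' Prediction accuracy stratified by residue-property ratio
#'
#' Assigns each peptide a property ratio (see [residue_property_ratio()]),
#' bins the ratios, and reports per-bin peptide count and mean prediction
#' accuracy.
#'
#' @param data Labeled peptide tibble (`id`, `sequence`, `label`).
#' @param predictions Tibble with columns `sample_id` and `.pred` covering
#'   every peptide in `data` (e.g. the `predictions` attribute of
#'   [independent_test()]).
#' @param property One of `"hydrophobic"`, `"hydrophilic"`, `"charged"`.
#' @param bin_width Ratio bin width (default 0.1).
#' @return A `property_report` tibble with columns `property`, `bin_lo`,
#'   `bin_hi`, `bin_mid`, `n`, `accuracy`.
#' @export
accuracy_by_residue_property <- function(data, predictions, property,
                                         bin_width = 0.1) {
  merged <- dplyr::inner_join(
    dplyr::rename(data, sample_id = "id"), predictions, by = "sample_id"
  )
  if (nrow(merged) < nrow(data)) {
    stop("predictions do not cover every peptide", call. = FALSE)
  }
  ratio <- residue_property_ratio(merged$sequence, property)
  edges <- round(seq(0, 1, by = bin_width), 10)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin <- cut(ratio, breaks = edges, include.lowest = TRUE, right = FALSE)
  bin[ratio == 1] <- levels(bin)[length(levels(bin))]
  out <- tibble::tibble(
    correct = as.integer(merged$label) == as.integer(merged$.pred),
    bin = bin
  ) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = if (dplyr::n() > 0) mean(.data$correct)
                     else NA_real_,
                     .groups = "drop") |>
    dplyr::mutate(
      property = property,
      bin_lo = edges[as.integer(.data$bin)],
      bin_hi = edges[as.integer(.data$bin) + 1L],
      bin_mid = (.data$bin_lo + .data$bin_hi) / 2
    ) |>
    dplyr::select("property", "bin_lo", "bin_hi", "bin_mid", "n", "accuracy")
  class(out) <- c("property_report", class(out))
  out
}

#' Class propensity of residue and dipeptide composition
#'
#' Mean amino-acid and dipeptide composition per class and their difference
#' (positive minus negative), sorted by absolute difference — the analysis
#' that shows which residues are enriched in the positive class.
#'
#' @param data Labeled peptide tibble with both classes present.
#' @return A tibble with columns `level` ("AAC"/"DPC"), `feature`,
#'   `mean_pos`, `mean_neg`, `diff`.
#' @export
composition_propensity <- function(data) {
  if (length(unique(data$label)) < 2) {
    stop("both classes required", call. = FALSE)
  }
  level_means <- function(encoder, level) {
    m <- t(vapply(data$sequence, encoder, encoder(data$sequence[1])))
    pos <- colMeans(m[data$label == 1L, , drop = FALSE])
    neg <- colMeans(m[data$label == 0L, , drop = FALSE])
    tibble::tibble(level = level, feature = colnames(m),
                   mean_pos = unname(pos), mean_neg = unname(neg),
                   diff = unname(pos - neg))
  }
  out <- dplyr::bind_rows(
    level_means(encode_aac, "AAC"),
    level_means(suppress_short_warnings(encode_dpc), "DPC")
  )
  dplyr::arrange(out, .data$level, dplyr::desc(abs(.data$diff)))
}

suppress_short_warnings <- function(f) {
  function(...) suppressWarnings(f(...))
}
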