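# End-to-end orchestration: encode -> normalize -> rank -> subset search ->
# tune -> cross-validate. Used by the command-line interface and by the
# acceptance checks.

#' Run the full classification pipeline on a labeled peptide dataset
#'
#' Encodes the dataset with the registry, ranks features with the
#' shadow-feature procedure (on the scaled development matrix), runs the
#' heuristic top-N subset search with the default models, tunes the requested
#' family on the selected subset, and evaluates it with repeated stratified
#' cross-validation. Normalization is re-fitted inside every CV training fold;
#' the up-front scaling is only used for the ranking step.
#'
#' @param dataset Labeled peptide tibble (`id`, `sequence`, `label`).
#' @param registry Descriptor registry (default [default_registry()]).
#' @param grid Subset-size grid (default `seq(50, 200, by = 10)`).
#' @param ranking_iters Shadow-ranking iterations (default 20).
#' @param search_repeats CV repetitions inside the subset search (default 1).
#' @param tune_family Family to tune on the selected subset (default
#'   `"svm"`); `NULL` tunes the family that won the subset search.
#' @param tune_trials TPE trials (default 20).
#' @param cv_folds Folds for the final cross-validation (default 10).
#' @param cv_repeats Repeats for the final cross-validation (default 2).
#' @param seed Integer seed driving every random step.
#' @return A list with elements `features` (encoded matrix), `ranking`,
#'   `search`, `tuning`, `spec`, `cv` (final `eval_report`), and `tpr_bins`
#'   (probability-bin report of the out-of-fold predictions).
#' @export
run_pipeline <- function(dataset, registry = default_registry(),
                         grid = seq(50, 200, by = 10),
                         ranking_iters = 20, search_repeats = 1,
                         tune_family = "svm", tune_trials = 20,
                         cv_folds = 10, cv_repeats = 2, seed = 1) {
  features <- encode_peptides(dataset, registry)
  scaler <- fit_quartile_scaler(features)
  scaled <- scale_features(features, scaler)
  ranking <- shadow_feature_ranking(scaled, n_iter = ranking_iters,
                                    seed = seed)
  search <- heuristic_subset_search(features, ranking, grid = grid,
                                    repeats = search_repeats, seed = seed)
  subset <- features[, c("sample_id", "label", search$features)]
  family <- tune_family %||% search$best$best_family[
    match(search$n_selected, search$best$N)]
  tuning <- tune_hyperparameters(subset, family, n_trials = tune_trials,
                                 cv_folds = cv_folds, seed = seed)
  spec <- spec_from_tuning(tuning)
  cv <- cross_validate(subset, spec, k = cv_folds, repeats = cv_repeats,
                       seed = seed)
  preds <- attr(cv, "predictions")
  tpr_bins <- tpr_by_probability_bins(preds$truth, preds$prob)
  list(features = features, ranking = ranking, search = search,
       tuning = tuning, spec = spec, cv = cv, tpr_bins = tpr_bins)
}
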