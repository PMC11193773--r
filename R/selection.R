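# Feature selection: a shadow-feature (Boruta-style) random-forest ranking
# followed by a heuristic top-N subset search over a grid of candidate sizes,
# scored by cross-validated MCC across the six classifier families.

#' Shadow-feature (Boruta-style) feature ranking
#'
#' Each iteration appends a permuted "shadow" copy of every feature, fits a
#' random forest, and marks a real feature as a hit when its importance
#' exceeds the maximum shadow importance. After `n_iter` iterations every
#' feature gets a two-sided binomial test of its hit count against chance
#' (p = 0.5): significantly more hits than chance confirms the feature,
#' significantly fewer rejects it, anything else stays tentative. The final
#' list is ordered confirmed > tentative > rejected, by mean importance
#' within each status, ties broken by feature name — so every feature of the
#' matrix appears exactly once and prefixes of the list are well-defined.
#'
#' @param data Feature-matrix tibble with a `label` column (both classes).
#' @param n_iter Number of shadow iterations (>= 10, default 30).
#' @param alpha Two-sided binomial test level (default 0.01).
#' @param num_trees Trees per random forest (default 300).
#' @param seed Integer seed; the ranking is deterministic given it.
#' @return A `feature_ranking` tibble with columns `rank`, `feature`,
#'   `importance` (mean across iterations), `hits`, `decision`
#'   (confirmed/tentative/rejected).
#' @export
shadow_feature_ranking <- function(data, n_iter = 30, alpha = 0.01,
                                   num_trees = 300, seed = 1) {
  stopifnot(n_iter >= 10)
  y <- as.integer(data$label)
  if (length(unique(y)) < 2) {
    stop("labels contain a single class", call. = FALSE)
  }
  feats <- feature_names(data)
  x <- as.matrix(data[, feats, drop = FALSE])
  set.seed(seed)
  n <- nrow(x)
  hits <- stats::setNames(integer(length(feats)), feats)
  imp_sum <- stats::setNames(numeric(length(feats)), feats)
  for (it in seq_len(n_iter)) {
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0(".shadow.", feats)
    xx <- cbind(x, shadow)
    rf <- ranger::ranger(
      x = xx, y = factor(y, levels = c(0, 1)),
      num.trees = num_trees, importance = "impurity",
      num.threads = 1, seed = sample.int(.Machine$integer.max, 1)
    )
    imp <- rf$variable.importance
    shadow_max <- max(imp[startsWith(names(imp), ".shadow.")])
    real <- imp[feats]
    hits <- hits + as.integer(real > shadow_max)
    imp_sum <- imp_sum + real
  }
  pvals <- vapply(hits, function(h)
    stats::binom.test(h, n_iter, 0.5)$p.value, numeric(1))
  decision <- ifelse(pvals < alpha & hits > n_iter / 2, "confirmed",
                     ifelse(pvals < alpha & hits < n_iter / 2, "rejected",
                            "tentative"))
  status_rank <- c(confirmed = 1L, tentative = 2L, rejected = 3L)
  out <- tibble::tibble(
    feature = feats,
    importance = imp_sum / n_iter,
    hits = as.integer(hits),
    decision = decision
  )
  out <- out[order(status_rank[out$decision], -out$importance, out$feature), ]
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Heuristic top-N feature-subset search
#'
#' For every candidate size `N` on the grid, takes the top-N prefix of the
#' ranking and scores it with repeated stratified 5-fold cross-validation for
#' each of the six default classifier families (quartile scaler re-fitted per
#' training fold). Per `N`, the best MCC over the families is recorded
#' (`Best_MCC_N = max_i MCC_N^i`); the selected subset is the prefix whose
#' best MCC is maximal over the grid, smallest `N` on ties. Family ties at a
#' given `N` are reported in the fixed precedence order of
#' [model_families()].
#'
#' @param data Feature-matrix tibble with a `label` column.
#' @param ranking A `feature_ranking` from [shadow_feature_ranking()].
#' @param grid Candidate subset sizes (default `seq(50, 200, by = 10)`,
#'   16 sizes); must not exceed the number of ranked features.
#' @param cv_folds CV folds (default 5).
#' @param repeats CV repetitions averaged per (N, family) (default 3).
#' @param families Family codes to benchmark (default all six).
#' @param seed Integer seed.
#' @return A `subset_search` object: `grid` (tibble `N` x `family` x `mcc`),
#'   `best` (per-N best MCC and family), `n_selected`, `features` (the
#'   selected prefix), `best_mcc`.
#' @export
heuristic_subset_search <- function(data, ranking,
                                    grid = seq(50, 200, by = 10),
                                    cv_folds = 5, repeats = 3,
                                    families = model_families(), seed = 1) {
  if (max(grid) > nrow(ranking)) {
    stop("grid size ", max(grid), " exceeds the ", nrow(ranking),
         " ranked features", call. = FALSE)
  }
  grid <- sort(unique(as.integer(grid)))
  cells <- tidyr::expand_grid(N = grid, family = families)
  mcc_vals <- purrr::pmap_dbl(cells, function(N, family) {
    prefix <- ranking$feature[seq_len(N)]
    sub <- data[, c(intersect(c("sample_id", "label"), names(data)), prefix)]
    spec <- make_default_model(family, seed = seed)
    scores <- vapply(seq_len(repeats), function(r) {
      preds <- tryCatch(
        cv_predictions(sub, spec, cv_folds, fold_seed = seed + 1000L * r),
        error = function(e) NULL
      )
      if (is.null(preds)) NA_real_
      else mcc_of(confusion_counts(preds$truth, preds$pred))
    }, numeric(1))
    mean(scores)
  })
  grid_tbl <- dplyr::mutate(cells, mcc = mcc_vals)
  best <- grid_tbl |>
    dplyr::mutate(family = factor(.data$family, levels = families)) |>
    dplyr::group_by(.data$N) |>
    dplyr::arrange(dplyr::desc(.data$mcc), .data$family, .by_group = TRUE) |>
    dplyr::summarise(best_mcc = max(.data$mcc, na.rm = TRUE),
                     best_family = as.character(dplyr::first(.data$family)),
                     .groups = "drop")
  j <- best$N[which.max(best$best_mcc)]  # which.max takes the first (smallest N)
  structure(list(
    grid = grid_tbl,
    best = best,
    n_selected = j,
    best_mcc = max(best$best_mcc),
    features = ranking$feature[seq_len(j)],
    settings = list(cv_folds = cv_folds, repeats = repeats, seed = seed,
                    families = families)
  ), class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat("<subset_search> grid ", min(x$best$N), "..", max(x$best$N), " (",
      nrow(x$best), " sizes x ", length(x$settings$families),
      " families); selected N = ", x$n_selected,
      " with best CV MCC = ", format(x$best_mcc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Export a subset-search result
#'
#' Writes the N x family MCC grid as CSV and a JSON summary (selected N, best
#' MCC, selected feature names).
#'
#' @param result A `subset_search`.
#' @param grid_path CSV path for the MCC grid.
#' @param summary_path JSON path for the summary.
#' @return Invisibly, the two paths.
#' @export
write_subset_search <- function(result, grid_path, summary_path) {
  utils::write.csv(result$grid, grid_path, row.names = FALSE)
  jsonlite::write_json(
    list(n_selected = result$n_selected, best_mcc = result$best_mcc,
         features = result$features),
    summary_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(grid_path, summary_path))
}
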