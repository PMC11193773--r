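# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a quartile scaler
#'
#' @param x A `quartile_scaler`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature`, `median`, `q1`, `q3`,
#'   `degenerate`, `scale`.
#' @export
tidy.quartile_scaler <- function(x, ...) x$params

#' @rdname tidy.quartile_scaler
#' @export
glance.quartile_scaler <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$params),
                 n_degenerate = sum(x$params$degenerate),
                 n_fit = x$n_fit)
}

#' Tidy a subset-search result
#'
#' @param x A `subset_search`.
#' @param ... Unused.
#' @return The N x family MCC grid as a tibble.
#' @export
tidy.subset_search <- function(x, ...) x$grid

#' @rdname tidy.subset_search
#' @export
glance.subset_search <- function(x, ...) {
  tibble::tibble(n_selected = x$n_selected, best_mcc = x$best_mcc,
                 best_family = x$best$best_family[match(x$n_selected, x$best$N)],
                 grid_sizes = nrow(x$best))
}

#' Tidy a tuning result
#'
#' @param x A `tune_result`.
#' @param ... Unused.
#' @return The trial log: `trial`, one column per hyperparameter, `score`,
#'   `status`.
#' @export
tidy.tune_result <- function(x, ...) {
  params <- dplyr::bind_rows(lapply(x$trials$params, function(p) {
    if (!length(p)) return(tibble::tibble(.rows = 1))
    tibble::as_tibble(p)
  }))
  dplyr::bind_cols(x$trials[, "trial"], params,
                   x$trials[, c("score", "status")])
}

#' @rdname tidy.tune_result
#' @export
glance.tune_result <- function(x, ...) {
  tibble::tibble(family = x$family, n_trials = nrow(x$trials),
                 n_complete = sum(x$trials$status == "complete"),
                 n_pruned = sum(x$trials$status == "pruned"),
                 best_score = x$best_score)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report` (from [compute_metrics()], [cross_validate()] or
#'   [independent_test()]).
#' @param ... Unused.
#' @return Long tibble with columns `metric`, `value`.
#' @export
tidy.eval_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  counts <- attr(x, "counts")
  out <- tibble::as_tibble(x)
  if (!is.null(counts)) out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  out
}

#' Tidy a feature ranking
#'
#' @param x A `feature_ranking`.
#' @param ... Unused.
#' @return The ranking as a plain tibble.
#' @export
tidy.feature_ranking <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "feature_ranking")
  out
}

#' @rdname tidy.feature_ranking
#' @export
glance.feature_ranking <- function(x, ...) {
  tibble::tibble(n_features = nrow(x),
                 n_confirmed = sum(x$decision == "confirmed"),
                 n_tentative = sum(x$decision == "tentative"),
                 n_rejected = sum(x$decision == "rejected"))
}
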