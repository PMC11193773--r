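# The six classifier families and their tuning. Families: SVM with RBF kernel
# (e1071), linear discriminant analysis (MASS), random forest and extremely
# randomized trees (ranger), gradient-boosted trees (xgboost) and elastic-net
# logistic regression (glmnet). All families expose class-1 probabilities;
# hard labels come from thresholding at 0.5.
#
# The reporting/tie-break precedence order of the families is the order of
# model_families().

#' Classifier families
#'
#' @return Character vector of the six family codes, in precedence order.
#' @export
model_families <- function() c("svm", "lda", "rf", "et", "gbt", "enet")

default_params <- function(family) {
  switch(family,
    svm  = list(cost = 1, gamma = NA_real_),  # gamma NA -> 1/n_features
    lda  = list(),
    rf   = list(num_trees = 500, mtry_frac = NA_real_, min_node = 1),
    et   = list(num_trees = 500, mtry_frac = NA_real_, min_node = 1),
    gbt  = list(nrounds = 200, eta = 0.1, max_depth = 6,
                subsample = 1, colsample = 1),
    enet = list(alpha = 0.5, lambda = 0.01),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

#' Construct a model specification with default hyperparameters
#'
#' @param family One of `"svm"` (RBF kernel), `"lda"`, `"rf"`, `"et"`,
#'   `"gbt"`, `"enet"`.
#' @param seed Integer seed consumed by stochastic learners.
#' @param params Named list of hyperparameter overrides.
#' @return A `model_spec` object.
#' @examples
#' make_default_model("svm")
#' @export
make_default_model <- function(family, seed = 1, params = list()) {
  defaults <- default_params(family)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults, seed = as.integer(seed),
                 threshold = 0.5),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  ps <- if (length(x$params))
    paste(names(x$params), vapply(x$params, format, character(1)),
          sep = "=", collapse = ", ") else "(no hyperparameters)"
  cat("<model_spec> ", x$family, ": ", ps, "\n", sep = "")
  invisible(x)
}

# Drop zero-variance columns (degenerate after robust scaling); LDA and
# glmnet cannot digest them. The kept set is stored with the fitted model.
usable_features <- function(x) {
  v <- apply(x, 2, stats::var)
  colnames(x)[v > 0]
}

#' Fit a model specification on a feature matrix
#'
#' Fits the family on all rows of `data` (features are expected to be scaled
#' already; the CV and independent-test drivers handle scaling). Zero-variance
#' feature columns are dropped at fit time and ignored at prediction time.
#'
#' @param data Feature-matrix tibble with a `label` column holding both
#'   classes.
#' @param spec A `model_spec`.
#' @return A fitted `aap_model` object with a [predict()] method.
#' @export
fit_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  y <- as.integer(data$label)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  x <- as.matrix(data[, feature_names(data), drop = FALSE])
  keep <- usable_features(x)
  if (!length(keep)) stop("no non-constant features to fit on", call. = FALSE)
  x <- x[, keep, drop = FALSE]
  p <- spec$params
  set.seed(spec$seed)
  fit <- switch(spec$family,
    svm = {
      gamma <- if (is.na(p$gamma)) 1 / ncol(x) else p$gamma
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = p$cost, gamma = gamma, probability = TRUE)
    },
    lda = suppressWarnings(MASS::lda(x, grouping = factor(y))),
    rf = {
      mtry <- if (is.na(p$mtry_frac)) floor(sqrt(ncol(x)))
              else max(1L, floor(p$mtry_frac * ncol(x)))
      ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                     num.trees = p$num_trees, mtry = min(mtry, ncol(x)),
                     min.node.size = p$min_node, probability = TRUE,
                     num.threads = 1, seed = spec$seed)
    },
    et = {
      mtry <- if (is.na(p$mtry_frac)) floor(sqrt(ncol(x)))
              else max(1L, floor(p$mtry_frac * ncol(x)))
      ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                     num.trees = p$num_trees, mtry = min(mtry, ncol(x)),
                     min.node.size = p$min_node, probability = TRUE,
                     splitrule = "extratrees", replace = FALSE,
                     sample.fraction = 1, num.threads = 1, seed = spec$seed)
    },
    gbt = xgboost::xgboost(
      x, factor(y, levels = c(0, 1)), objective = "binary:logistic",
      nrounds = p$nrounds, learning_rate = p$eta, max_depth = p$max_depth,
      subsample = p$subsample, colsample_bytree = p$colsample,
      nthreads = 1, seed = spec$seed, verbosity = 0
    ),
    enet = glmnet::glmnet(x, factor(y, levels = c(0, 1)),
                          family = "binomial", alpha = p$alpha,
                          lambda = p$lambda),
    stop("unknown model family: ", spec$family, call. = FALSE)
  )
  structure(list(spec = spec, fit = fit, features = keep,
                 threshold = spec$threshold),
            class = "aap_model")
}

#' Predict with a fitted model
#'
#' @param object An `aap_model`.
#' @param data Feature-matrix tibble containing at least the model's feature
#'   columns.
#' @param ... Unused.
#' @return A tibble with columns `.prob` (class-1 probability) and `.pred`
#'   (integer label; 1 iff `.prob >= threshold`).
#' @export
predict.aap_model <- function(object, data, ...) {
  x <- as.matrix(data[, object$features, drop = FALSE])
  prob <- switch(object$spec$family,
    svm = {
      pr <- stats::predict(object$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    lda = stats::predict(object$fit, x)$posterior[, "1"],
    rf = stats::predict(object$fit, data = x,
                        num.threads = 1)$predictions[, "1"],
    et = stats::predict(object$fit, data = x,
                        num.threads = 1)$predictions[, "1"],
    gbt = stats::predict(object$fit, x),
    enet = as.numeric(stats::predict(object$fit, x, type = "response"))
  )
  prob <- pmin(pmax(as.numeric(prob), 0), 1)
  tibble::tibble(.prob = prob,
                 .pred = as.integer(prob >= object$threshold))
}

#' Fit the final model on the complete development set
#'
#' The retrain-before-independent-test step: fits `spec` (tuned or default)
#' on every row of the development matrix.
#'
#' @inheritParams fit_model
#' @return A fitted `aap_model`.
#' @export
fit_final <- function(data, spec) fit_model(data, spec)

#' Default hyperparameter search spaces
#'
#' Declarative per-family search spaces used by [tune_hyperparameters()].
#' Each entry is `list(type, lower, upper, log)` for numeric parameters,
#' `list(type = "int", ...)` for integers, or `list(type = "cat", values)`.
#'
#' @param family Family code.
#' @return Named list of parameter definitions.
#' @export
default_search_space <- function(family) {
  num <- function(lo, hi, log = FALSE) list(type = "num", lower = lo,
                                            upper = hi, log = log)
  int <- function(lo, hi) list(type = "int", lower = lo, upper = hi)
  switch(family,
    svm  = list(cost = num(1e-2, 1e3, log = TRUE),
                gamma = num(1e-4, 1e1, log = TRUE)),
    lda  = list(),
    rf   = list(num_trees = int(100, 1000), mtry_frac = num(0.05, 1),
                min_node = int(1, 8)),
    et   = list(num_trees = int(100, 1000), mtry_frac = num(0.05, 1),
                min_node = int(1, 8)),
    gbt  = list(nrounds = int(100, 1000), eta = num(1e-3, 0.3, log = TRUE),
                max_depth = int(2, 10), subsample = num(0.5, 1),
                colsample = num(0.5, 1)),
    enet = list(alpha = num(0, 1), lambda = num(1e-4, 1, log = TRUE)),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

sample_param <- function(def) {
  switch(def$type,
    num = if (isTRUE(def$log))
      exp(stats::runif(1, log(def$lower), log(def$upper)))
    else stats::runif(1, def$lower, def$upper),
    int = sample(seq(def$lower, def$upper), 1),
    cat = sample(def$values, 1)
  )
}

# One-dimensional kernel density score mixed with a uniform floor, evaluated
# in the (possibly log-) transformed coordinate.
kde_score <- function(x, points, lo, hi, eps = 0.1) {
  if (!length(points)) return(rep(1 / (hi - lo), length(x)))
  bw <- 1.06 * stats::sd(points) * length(points)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) bw <- (hi - lo) / 20
  dens <- vapply(x, function(xi) mean(stats::dnorm(xi, points, bw)),
                 numeric(1))
  (1 - eps) * dens + eps / (hi - lo)
}

# TPE proposal for one parameter given completed trials.
propose_param <- function(name, def, trials, gamma = 0.25, n_candidates = 24) {
  done <- trials[!is.na(trials$score), , drop = FALSE]
  if (def$type == "cat") {
    n_good <- max(1L, ceiling(gamma * nrow(done)))
    good <- utils::head(done[order(-done$score), ], n_good)
    counts_g <- table(factor(vapply(good$params, `[[`, good$params[[1]][[name]],
                                    name), levels = def$values))
    probs <- (as.numeric(counts_g) + 1)
    return(sample(def$values, 1, prob = probs / sum(probs)))
  }
  tf <- function(v) if (isTRUE(def$log)) log(v) else v
  itf <- function(v) if (isTRUE(def$log)) exp(v) else v
  vals <- vapply(done$params, function(p) tf(as.numeric(p[[name]])),
                 numeric(1))
  n_good <- max(1L, ceiling(gamma * length(vals)))
  ord <- order(-done$score)
  good <- vals[ord[seq_len(n_good)]]
  bad <- vals[ord[-seq_len(n_good)]]
  lo <- tf(def$lower); hi <- tf(def$upper)
  bw <- 1.06 * stats::sd(good) * length(good)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) bw <- (hi - lo) / 20
  cand <- stats::rnorm(n_candidates, sample(good, n_candidates, replace = TRUE), bw)
  cand <- pmin(pmax(cand, lo), hi)
  score <- kde_score(cand, good, lo, hi) / kde_score(cand, bad, lo, hi)
  best <- itf(cand[which.max(score)])
  if (def$type == "int") best <- as.integer(round(best))
  best
}

#' Tune hyperparameters with a tree-structured Parzen estimator
#'
#' Sequential model-based maximization of the mean stratified-CV Matthews
#' correlation coefficient. The first `n_startup` trials sample the space at
#' random; later trials split completed trials into good/bad sets at the
#' `gamma` quantile of the score and, per parameter, propose the candidate
#' maximizing the good/bad density ratio (Gaussian kernel densities with a
#' uniform floor). A median rule prunes unpromising trials after
#' `prune_after` folds once enough trials have completed. Failed folds mark
#' the trial failed; failed/pruned trials are excluded from the best.
#'
#' @param data Feature-matrix tibble with a `label` column.
#' @param family Family code (see [model_families()]).
#' @param space Search space (default [default_search_space()]).
#' @param n_trials Number of trials (default 100).
#' @param cv_folds CV folds per trial (default 10).
#' @param seed Integer seed; the whole trial log is deterministic given it.
#' @param gamma Good/bad split quantile (default 0.25).
#' @param n_startup Random startup trials before TPE proposals (default 10).
#' @param prune Enable median-rule pruning (default TRUE).
#' @param prune_after Folds evaluated before the pruning check (default 3).
#' @return A `tune_result` with the trial log, best parameters and best score.
#' @export
tune_hyperparameters <- function(data, family,
                                 space = default_search_space(family),
                                 n_trials = 100, cv_folds = 10, seed = 1,
                                 gamma = 0.25, n_startup = 10,
                                 prune = TRUE, prune_after = 3) {
  stopifnot(n_trials >= 1)
  if (!length(space)) {
    # families without tunable parameters: a single default trial
    spec <- make_default_model(family, seed = seed)
    score <- mean(cv_fold_scores(data, spec, cv_folds, seed))
    trials <- tibble::tibble(trial = 1L, params = list(list()),
                             score = score, status = "complete")
    return(new_tune_result(family, trials, list(), score, seed))
  }
  set.seed(seed)
  trials <- tibble::tibble(trial = integer(), params = list(),
                           score = numeric(), status = character())
  fold_history <- list()  # per completed trial: cumulative fold-mean curve
  for (t in seq_len(n_trials)) {
    params <- if (t <= n_startup || sum(!is.na(trials$score)) < 5) {
      lapply(space, sample_param)
    } else {
      stats::setNames(
        lapply(names(space), function(nm)
          propose_param(nm, space[[nm]], trials, gamma)),
        names(space)
      )
    }
    spec <- make_default_model(family, seed = seed + t, params = params)
    scores <- tryCatch(
      cv_fold_scores(data, spec, cv_folds, fold_seed = seed,
                     prune_check = if (prune) {
                       function(running_mean, fold_i) {
                         if (fold_i < prune_after || length(fold_history) < 5)
                           return(FALSE)
                         ref <- vapply(fold_history, function(h)
                           h[min(fold_i, length(h))], numeric(1))
                         running_mean < stats::median(ref)
                       }
                     } else NULL),
      error = function(e) e
    )
    if (inherits(scores, "error")) {
      trials <- dplyr::add_row(trials, trial = t, params = list(params),
                               score = NA_real_, status = "failed")
    } else if (isTRUE(attr(scores, "pruned"))) {
      trials <- dplyr::add_row(trials, trial = t, params = list(params),
                               score = NA_real_, status = "pruned")
    } else {
      trials <- dplyr::add_row(trials, trial = t, params = list(params),
                               score = mean(scores), status = "complete")
      fold_history[[length(fold_history) + 1L]] <- cumsum(scores) /
        seq_along(scores)
    }
  }
  done <- trials[trials$status == "complete", , drop = FALSE]
  if (!nrow(done)) stop("all tuning trials failed", call. = FALSE)
  best <- done[which.max(done$score), ]
  new_tune_result(family, trials, best$params[[1]], best$score, seed)
}

new_tune_result <- function(family, trials, best_params, best_score, seed) {
  structure(list(family = family, trials = trials,
                 best_params = best_params, best_score = best_score,
                 seed = seed),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat("<tune_result> ", x$family, ": ", nrow(x$trials), " trials (",
      sum(x$trials$status == "complete"), " complete), best CV MCC = ",
      format(x$best_score, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Model spec from a tuning result
#'
#' @param result A `tune_result`.
#' @param seed Seed for the resulting spec (default: the tuning seed).
#' @return A `model_spec` with the best hyperparameters.
#' @export
spec_from_tuning <- function(result, seed = result$seed) {
  make_default_model(result$family, seed = seed, params = result$best_params)
}

# Per-fold MCC scores for one spec (scaler re-fit per fold). Used by tuning;
# supports early pruning via prune_check(running_mean, fold_index).
cv_fold_scores <- function(data, spec, k, fold_seed, prune_check = NULL) {
  labels <- data$label
  set.seed(fold_seed)
  folds <- stratified_folds(labels, k)
  scores <- numeric(0)
  for (f in seq_len(k)) {
    tr <- data[folds != f, , drop = FALSE]
    te <- data[folds == f, , drop = FALSE]
    if (length(unique(te$label)) < 1 || length(unique(tr$label)) < 2) {
      stop("degenerate CV fold", call. = FALSE)
    }
    scaler <- fit_quartile_scaler(tr)
    model <- fit_model(scale_features(tr, scaler), spec)
    pr <- predict(model, scale_features(te, scaler))
    scores[f] <- mcc_of(confusion_counts(te$label, pr$.pred))
    if (!is.null(prune_check) &&
        prune_check(mean(scores[seq_len(f)]), f)) {
      out <- scores[seq_len(f)]
      attr(out, "pruned") <- TRUE
      return(out)
    }
  }
  scores
}
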