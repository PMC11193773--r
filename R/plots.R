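# ggplot2 visualizations for the main result types.

#' Plot a subset-search MCC grid
#'
#' MCC versus candidate subset size, one line per classifier family, with the
#' selected size circled.
#'
#' @param object A `subset_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subset_search <- function(object, ...) {
  best_row <- object$best[object$best$N == object$n_selected, ]
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$N, y = .data$mcc,
                               colour = .data$family)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::annotate("point", x = best_row$N, y = best_row$best_mcc,
                      shape = 21, size = 4, colour = "red") +
    ggplot2::labs(x = "Number of top-ranked features",
                  y = "Cross-validated MCC", colour = "Model") +
    ggplot2::theme_minimal()
}

#' Plot a tuning trajectory
#'
#' Trial score over the trial index with the running best overlaid.
#'
#' @param object A `tune_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tune_result <- function(object, ...) {
  df <- object$trials
  df$running_best <- cummax(ifelse(is.na(df$score), -Inf, df$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$score,
                                     shape = .data$status), na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$running_best),
                       colour = "steelblue") +
    ggplot2::labs(x = "Trial", y = "CV MCC",
                  title = paste("TPE tuning:", object$family)) +
    ggplot2::theme_minimal()
}

#' Plot the true-positive rate by probability bin
#'
#' Bars show the number of sequences per prediction-probability bin; the line
#' shows the bin-wise true-positive rate.
#'
#' @param object A `prob_bin_report` from [tpr_by_probability_bins()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prob_bin_report <- function(object, ...) {
  df <- object[object$n > 0, ]
  scale_f <- max(object$n)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n), fill = "grey80",
                      width = 0.08) +
    ggplot2::geom_line(data = df,
                       ggplot2::aes(y = .data$tpr * scale_f),
                       colour = "firebrick") +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(y = .data$tpr * scale_f),
                        colour = "firebrick") +
    ggplot2::scale_y_continuous(
      name = "Sequences",
      sec.axis = ggplot2::sec_axis(~ . / scale_f,
                                   name = "True positive rate")
    ) +
    ggplot2::labs(x = "Prediction probability") +
    ggplot2::theme_minimal()
}

#' Plot accuracy by residue-property ratio
#'
#' @param object A `property_report` from [accuracy_by_residue_property()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.property_report <- function(object, ...) {
  df <- object[object$n > 0, ]
  scale_f <- max(object$n)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n), fill = "grey80",
                      width = 0.08) +
    ggplot2::geom_line(data = df,
                       ggplot2::aes(y = .data$accuracy * scale_f),
                       colour = "navy") +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(y = .data$accuracy * scale_f),
                        colour = "navy") +
    ggplot2::scale_y_continuous(
      name = "Peptides",
      sec.axis = ggplot2::sec_axis(~ . / scale_f, name = "Mean accuracy")
    ) +
    ggplot2::labs(x = paste(unique(object$property), "residue ratio")) +
    ggplot2::theme_minimal()
}

#' Plot class propensity of residue composition
#'
#' Positive-minus-negative mean composition differences, most discriminating
#' first.
#'
#' @param propensity Output of [composition_propensity()].
#' @param level `"AAC"` (default) or `"DPC"`.
#' @param top Number of features to show (default 20).
#' @return A ggplot object.
#' @export
plot_propensity <- function(propensity, level = "AAC", top = 20) {
  df <- propensity[propensity$level == level, ]
  df <- utils::head(df, top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff, y = .data$feature,
                                   fill = .data$diff > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Mean composition difference (positive - negative)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
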