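# Robust quartile normalization: y = (x - median(X)) / (Q3(X) - Q1(X)),
# fitted on training data only. Quartiles use the linear-interpolation
# convention (stats::quantile type 7).

#' Fit a robust quartile scaler
#'
#' Computes, per feature, the median, first and third quartile on the training
#' matrix. Features with zero interquartile range are flagged degenerate and
#' get a fallback divisor of 1 (center-only scaling), so the feature layout
#' stays stable.
#'
#' @param data Feature-matrix tibble (columns `sample_id`, optional `label`,
#'   then numeric features) with at least 2 rows.
#' @return A `quartile_scaler` object.
#' @examples
#' m <- tibble::tibble(sample_id = letters[1:5], f = 1:5)
#' s <- fit_quartile_scaler(m)
#' scale_features(m, s)$f   # -1 -0.5 0 0.5 1
#' @export
fit_quartile_scaler <- function(data) {
  feats <- feature_names(data)
  if (nrow(data) < 2L || length(feats) == 0L) {
    stop("need at least 2 samples and 1 feature to fit a scaler",
         call. = FALSE)
  }
  x <- as.matrix(data[, feats, drop = FALSE])
  qs <- apply(x, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE, type = 7)
  iqr <- qs[3, ] - qs[1, ]
  params <- tibble::tibble(
    feature = feats,
    median = unname(qs[2, ]),
    q1 = unname(qs[1, ]),
    q3 = unname(qs[3, ]),
    degenerate = unname(iqr == 0),
    scale = unname(ifelse(iqr == 0, 1, iqr))
  )
  structure(list(params = params, n_fit = nrow(data)),
            class = "quartile_scaler")
}

#' Apply a fitted quartile scaler
#'
#' Transforms each feature with `(x - median) / (Q3 - Q1)` using the
#' training-fitted parameters (fallback divisor 1 for degenerate features).
#' On the training matrix itself, every non-degenerate feature ends up with
#' median 0 and interquartile range 1.
#'
#' @param data Feature-matrix tibble whose feature columns match the scaler's.
#' @param scaler A `quartile_scaler` from [fit_quartile_scaler()].
#' @return The transformed tibble, same shape as the input.
#' @export
scale_features <- function(data, scaler) {
  stopifnot(inherits(scaler, "quartile_scaler"))
  feats <- feature_names(data)
  p <- scaler$params
  missing <- setdiff(p$feature, feats)
  extra <- setdiff(feats, p$feature)
  if (length(missing) || length(extra)) {
    stop("feature mismatch between matrix and scaler",
         if (length(missing)) paste0("; absent from matrix: ",
           paste(utils::head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; unseen by scaler: ",
           paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  x <- as.matrix(data[, p$feature, drop = FALSE])
  y <- sweep(sweep(x, 2, p$median, "-"), 2, p$scale, "/")
  out <- data
  out[, p$feature] <- tibble::as_tibble(y)
  out
}

#' Serialize / restore a quartile scaler as TSV text
#'
#' @param scaler A `quartile_scaler`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `quartile_scaler` for the reader.
#' @export
write_scaler <- function(scaler, path) {
  utils::write.table(scaler$params, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  p <- tibble::as_tibble(
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = c("character", rep("numeric", 3),
                                     "logical", "numeric"))
  )
  structure(list(params = p, n_fit = NA_integer_), class = "quartile_scaler")
}

#' @export
print.quartile_scaler <- function(x, ...) {
  cat("<quartile_scaler> ", nrow(x$params), " features",
      if (!is.na(x$n_fit)) paste0(", fitted on ", x$n_fit, " samples"),
      "; ", sum(x$params$degenerate), " degenerate\n", sep = "")
  invisible(x)
}
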