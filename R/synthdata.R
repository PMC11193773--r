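# Synthetic labeled peptide datasets and synthetic feature matrices with
# known ground truth, so every pipeline stage is testable without external
# downloads. The peptide generator emulates the structure of curated
# anti-angiogenic peptide collections: two classes of ~100 peptides,
# class-biased residue composition (C, P, R, S, W enriched in positives;
# A, E, I, L, V in negatives), lengths ~10-50 (or exactly 15 for the
# N-terminal profile).

#' Synthetic peptide generator configuration
#'
#' @param n_pos,n_neg Peptides per class (default 100 each).
#' @param length_range Inclusive length range, drawn uniformly (default
#'   `c(10, 50)`).
#' @param pos_bias Residues enriched in positives (default C, P, R, S, W).
#' @param neg_bias Residues enriched in negatives (default A, E, I, L, V).
#' @param enrichment Multiplicative enrichment factor applied to the biased
#'   residues of each class before renormalizing (default 5; 1 = null case
#'   with indistinguishable classes).
#' @param base Baseline residue weights (default uniform over the 20
#'   residues); a named numeric vector to supply a background composition.
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_pos = 100, n_neg = 100,
                             length_range = c(10, 50),
                             pos_bias = c("C", "P", "R", "S", "W"),
                             neg_bias = c("A", "E", "I", "L", "V"),
                             enrichment = 5,
                             base = NULL, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  if (enrichment <= 0) stop("enrichment factor must be > 0", call. = FALSE)
  if (is.null(base)) {
    base <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  } else {
    stopifnot(setequal(names(base), AA_ALPHABET), all(base > 0))
    base <- base[AA_ALPHABET] / sum(base)
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, length_range = length_range,
                 pos_bias = pos_bias, neg_bias = neg_bias,
                 enrichment = enrichment, base = base, seed = seed),
            class = "generator_config")
}

#' Preset generator profiles
#'
#' `"fulllength"` mimics curated full-length collections (two classes of 100,
#' lengths 10-50); `"nterm15"` mimics N-terminal datasets (every sequence
#' exactly 15 residues).
#'
#' @param profile `"fulllength"` or `"nterm15"`.
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
synth_profile <- function(profile = c("fulllength", "nterm15"), ...) {
  profile <- match.arg(profile)
  args <- list(...)
  if (profile == "nterm15" && is.null(args$length_range)) {
    args$length_range <- c(15, 15)
  }
  do.call(generator_config, args)
}

class_weights <- function(cfg, positive) {
  w <- cfg$base
  bias <- if (positive) cfg$pos_bias else cfg$neg_bias
  w[bias] <- w[bias] * cfg$enrichment
  w / sum(w)
}

#' Generate a labeled synthetic peptide dataset
#'
#' Residues are drawn from class-specific multinomials (the baseline
#' composition re-weighted by the enrichment factor on the class's biased
#' residues); lengths are uniform over the configured range. Deterministic
#' given the config seed.
#'
#' @param cfg A `generator_config`.
#' @return A labeled peptide tibble (`id`, `sequence`, `label`) with the
#'   config stored in the `"generator"` attribute.
#' @export
generate_peptide_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  gen_class <- function(n, prefix, positive) {
    w <- class_weights(cfg, positive)
    len_choices <- seq(cfg$length_range[1], cfg$length_range[2])
    lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
    seqs <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = w), collapse = ""),
      character(1))
    tibble::tibble(
      id = sprintf("%s_%03d", prefix, seq_len(n)),
      sequence = seqs,
      label = as.integer(positive)
    )
  }
  out <- dplyr::bind_rows(gen_class(cfg$n_pos, "pos", TRUE),
                          gen_class(cfg$n_neg, "neg", FALSE))
  attr(out, "generator") <- cfg
  attr(out, "dataset_name") <- "synthetic"
  out
}

#' Generate a synthetic feature matrix with known informative features
#'
#' Balanced two-class design: informative columns get a class mean shift of
#' `effect` standard deviations on top of unit Gaussian noise; noise columns
#' are pure unit Gaussian noise. Ground-truth informative names are returned,
#' supporting parameter-recovery tests of the selection module.
#'
#' @param n_samples Total samples (split evenly between classes).
#' @param n_informative Number of informative features (>= 1).
#' @param n_noise Number of pure-noise features.
#' @param effect Class mean shift in noise SD units (default 3; 0 makes the
#'   informative columns indistinguishable from noise).
#' @param seed Integer seed.
#' @return A list: `data` (feature-matrix tibble with `sample_id`, `label`,
#'   features), `informative` (character vector of informative column names).
#' @export
generate_feature_matrix <- function(n_samples = 200, n_informative = 10,
                                    n_noise = 490, effect = 3, seed = 1) {
  stopifnot(n_informative >= 1)
  set.seed(seed)
  n_pos <- ceiling(n_samples / 2)
  y <- c(rep(1L, n_pos), rep(0L, n_samples - n_pos))
  inf_names <- sprintf("inf_%02d", seq_len(n_informative))
  noise_names <- if (n_noise > 0) sprintf("noise_%03d", seq_len(n_noise))
                 else character()
  x_inf <- matrix(stats::rnorm(n_samples * n_informative), n_samples) +
    outer(y, rep(effect, n_informative))
  x_noise <- matrix(stats::rnorm(n_samples * n_noise), n_samples)
  mat <- cbind(x_inf, x_noise)
  colnames(mat) <- c(inf_names, noise_names)
  data <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s_%03d", seq_len(n_samples)),
                   label = y),
    tibble::as_tibble(mat)
  )
  list(data = data, informative = inf_names)
}

#' Write a synthetic dataset as FASTA pairs plus a label table
#'
#' Writes `<stem>_pos.fasta`, `<stem>_neg.fasta` and `<stem>_labels.tsv`, so
#' synthetic data flows through the same file-based path as real data.
#'
#' @param data Labeled peptide tibble.
#' @param stem Output path stem.
#' @return Invisibly, the three paths.
#' @export
write_dataset_files <- function(data, stem) {
  pos <- data[data$label == 1L, c("id", "sequence")]
  neg <- data[data$label == 0L, c("id", "sequence")]
  paths <- c(paste0(stem, "_pos.fasta"), paste0(stem, "_neg.fasta"),
             paste0(stem, "_labels.tsv"))
  write_fasta(pos, paths[1])
  write_fasta(neg, paths[2])
  utils::write.table(data[, c("id", "label")], paths[3], sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(paths)
}
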