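#' Read peptide sequences from a FASTA file
#'
#' Parses a FASTA file of peptide sequences into a tibble with one row per
#' record. Sequences are upper-cased and validated against the canonical
#' 20-letter amino-acid alphabet.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE` (default) any record containing a non-canonical
#'   residue (anything outside `ACDEFGHIKLMNPQRSTVWY`) is an error. If
#'   `FALSE`, offending records are dropped with a warning, because every
#'   downstream descriptor assumes the 20-letter alphabet.
#' @return A tibble with columns `id` and `sequence`, in file order. An empty
#'   file yields a zero-row tibble.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDE", ">p2", "WWW"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) | seq_along(lines) == 0
  line_no <- seq_along(lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  lines <- lines[nonblank]
  line_no <- line_no[nonblank]
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    stop("malformed FASTA: line ", line_no[1],
         " precedes the first '>' header", call. = FALSE)
  }
  rec_idx <- cumsum(is_header)
  ids <- trimws(sub("^>", "", lines[is_header]))
  ids <- sub("\\s.*$", "", ids)
  empty_id <- which(!nzchar(ids))
  if (length(empty_id)) {
    stop("malformed FASTA: empty header at line ",
         line_no[is_header][empty_id[1]], call. = FALSE)
  }
  seqs <- vapply(
    split(lines[!is_header], rec_idx[!is_header]),
    function(x) paste(x, collapse = ""), character(1)
  )
  missing_body <- setdiff(as.character(seq_along(ids)), names(seqs))
  if (length(missing_body)) {
    i <- as.integer(missing_body[1])
    stop("malformed FASTA: empty record '", ids[i], "' at line ",
         line_no[is_header][i], call. = FALSE)
  }
  seqs <- toupper(gsub("\\s", "", seqs[as.character(seq_along(ids))]))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad)) {
    if (strict) {
      stop("non-canonical residue in record '", ids[which(bad)[1]],
           "' (use strict = FALSE to drop such records)", call. = FALSE)
    }
    warning("dropping ", sum(bad), " record(s) with non-canonical residues: ",
            paste(utils::head(ids[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", call. = FALSE)
    ids <- ids[!bad]
    seqs <- seqs[!bad]
  }
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write peptide sequences to a FASTA file
#'
#' @param data A tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @param wrap Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, wrap = 60) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  out <- unlist(purrr::map2(data$id, data$sequence, function(id, s) {
    body <- substring(s, seq(1, nchar(s), wrap),
                      pmin(seq(1, nchar(s), wrap) + wrap - 1, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Combine positive and negative peptides into a labeled dataset
#'
#' Builds the standard two-class design: positives (label 1, e.g. validated
#' anti-angiogenic peptides) followed by negatives (label 0). Identifier
#' collisions across the two inputs are resolved by prefixing with `pos_` /
#' `neg_` so that no record is lost.
#'
#' @param positives,negatives Tibbles with columns `id`, `sequence`.
#' @param name Dataset name, stored as the `"dataset_name"` attribute.
#' @return A tibble with columns `id`, `sequence`, `label` (integer 1/0).
#' @export
make_labeled_dataset <- function(positives, negatives, name = "dataset") {
  if (nrow(positives) + nrow(negatives) == 0L) {
    stop("both peptide sets are empty", call. = FALSE)
  }
  pos <- dplyr::mutate(positives, label = 1L)
  neg <- dplyr::mutate(negatives, label = 0L)
  out <- dplyr::bind_rows(pos, neg)
  dup <- duplicated(out$id) | duplicated(out$id, fromLast = TRUE)
  if (any(dup)) {
    out$id[dup] <- paste0(ifelse(out$label[dup] == 1L, "pos_", "neg_"),
                          out$id[dup])
  }
  if (anyDuplicated(out$id)) {
    out$id <- make.unique(out$id, sep = "_")
  }
  attr(out, "dataset_name") <- name
  out
}

#' Read a two-column label table
#'
#' Alternative to paired FASTA files: a TSV with columns `id` and `label`
#' (1 = positive, 0 = negative), no header required.
#'
#' @param path Path to a tab-separated file.
#' @return Tibble with columns `id` (character) and `label` (integer).
#' @export
read_label_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  if (nrow(raw) && identical(tolower(raw$id[1]), "id")) {
    raw <- raw[-1, , drop = FALSE]
    raw$label <- as.integer(raw$label)
  }
  if (!all(raw$label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Attach labels from a label table to peptides
#'
#' @param peptides Tibble with `id`, `sequence`.
#' @param labels Tibble with `id`, `label` (from [read_label_table()]).
#' @param name Dataset name.
#' @return Labeled dataset tibble (`id`, `sequence`, `label`).
#' @export
attach_labels <- function(peptides, labels, name = "dataset") {
  missing <- setdiff(peptides$id, labels$id)
  if (length(missing)) {
    stop("no label for peptide(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(peptides, labels, by = "id")
  out$label <- as.integer(out$label)
  attr(out, "dataset_name") <- name
  out
}

#' Truncate peptides to their N-terminal residues
#'
#' Replaces each sequence by its first `min(n, length)` residues, emulating
#' N-terminus datasets built from the first 15 amino acids of each peptide.
#' Labels and ids are unchanged; the operation is idempotent for fixed `n`.
#'
#' @param data Labeled dataset tibble (or any tibble with a `sequence` column).
#' @param n Number of N-terminal residues to keep (default 15).
#' @return The input tibble with truncated sequences.
#' @export
truncate_n_terminus <- function(data, n = 15) {
  stopifnot(n >= 1)
  dplyr::mutate(data, sequence = substr(.data$sequence, 1L, n))
}

#' Stratified development/test split
#'
#' Splits a labeled dataset into a development and a test part, preserving
#' class proportions. Per class, the test part receives
#' `floor((1 - fraction) * class_size)` peptides and the remainder stays in
#' the development part, so a 105+107 dataset at `fraction = 0.8` yields a
#' 170-peptide development set and a 42-peptide test set.
#'
#' @param data Labeled dataset tibble.
#' @param fraction Development-set proportion, strictly between 0 and 1.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with elements `dev` and `test`, both labeled dataset
#'   tibbles; their union is the input and they are disjoint.
#' @export
stratified_split <- function(data, fraction = 0.8, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  sizes <- table(data$label)
  if (any(sizes < 2)) {
    stop("each class needs at least 2 members to split", call. = FALSE)
  }
  set.seed(seed)
  test_idx <- unlist(lapply(sort(unique(data$label)), function(cl) {
    idx <- which(data$label == cl)
    # round before floor so 0.2 * 105 is 21, not 20.999...
    n_test <- floor(round((1 - fraction) * length(idx), 9))
    if (n_test == 0) integer() else sample(idx, n_test)
  }))
  dev <- data[setdiff(seq_len(nrow(data)), test_idx), , drop = FALSE]
  test <- data[sort(test_idx), , drop = FALSE]
  attr(dev, "dataset_name") <- paste0(attr(data, "dataset_name") %||% "dataset", "_dev")
  attr(test, "dataset_name") <- paste0(attr(data, "dataset_name") %||% "dataset", "_test")
  list(dev = dev, test = test)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
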