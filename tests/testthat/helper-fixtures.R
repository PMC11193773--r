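# Shared fixtures, built in code at test time.

# A tiny labeled peptide set with hand-chosen sequences.
tiny_dataset <- function() {
  tibble::tibble(
    id = c("p1", "p2", "p3", "n1", "n2"),
    sequence = c("ACDEFGHIKL", "CCPWSRRSWC", "MNPQRSTVWY",
                 "AAEILVAAEL", "LIVEALIVEA"),
    label = c(1L, 1L, 1L, 0L, 0L)
  )
}

# Random valid peptides for property tests.
random_peptides <- function(n, min_len = 5, max_len = 12, seed = 42) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    L <- sample(seq(min_len, max_len), 1)
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, character(1))
}

write_tmp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

# Brute-force k-spaced pair counting oracle (independent of the encoder).
oracle_kspaced <- function(sequence, k, alphabet = AA_ALPHABET) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  counts <- matrix(0, length(alphabet), length(alphabet),
                   dimnames = list(alphabet, alphabet))
  n <- 0
  for (i in seq_len(L)) {
    j <- i + k + 1
    if (j <= L) {
      counts[chars[i], chars[j]] <- counts[chars[i], chars[j]] + 1
      n <- n + 1
    }
  }
  if (n > 0) counts / n else counts
}

# Linearly separable feature matrix for model checks.
separable_matrix <- function(n = 60, p = 4, margin = 6, seed = 99) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  x <- matrix(stats::rnorm(n * p), n) + outer(y, rep(margin, p))
  colnames(x) <- sprintf("f%02d", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)), label = y),
    tibble::as_tibble(x)
  )
}
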