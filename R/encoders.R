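# Peptide descriptor encoders. Every encoder maps one sequence (a string over
# the 20-letter alphabet) to a fixed-length named numeric vector; the registry
# in registry.R assembles them into the default 58-type / 4335-value encoding.
#
# Short-sequence convention: any gap/lag/correlation term that cannot be
# computed for a short peptide is 0, signalled with a warning (collected and
# summarized by encode_peptides()), never an error mid-pipeline.

seq_chars <- function(sequence) strsplit(sequence, "")[[1]]

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  if (grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), sequence)) {
    stop("sequence contains non-canonical residues", call. = FALSE)
  }
  invisible(sequence)
}

short_seq_warning <- function(what) {
  warning(what, " set to 0 (sequence too short)", call. = FALSE)
}

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 residues; the vector sums to 1.
#'
#' @param sequence Peptide sequence string.
#' @return Named numeric vector of length 20.
#' @examples
#' encode_aac("ACDC")
#' @export
encode_aac <- function(sequence) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.vector(counts) / length(chars), AA_ALPHABET)
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each of the 400 ordered residue pairs among the `L - 1`
#' adjacent pairs. A single-residue peptide yields an all-zero vector with a
#' warning.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400.
#' @export
encode_dpc <- function(sequence) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  pairs <- paste0(rep(AA_ALPHABET, each = 20), AA_ALPHABET)
  if (length(chars) < 2L) {
    short_seq_warning("DPC")
    return(stats::setNames(numeric(400), pairs))
  }
  di <- paste0(chars[-length(chars)], chars[-1])
  counts <- table(factor(di, levels = pairs))
  stats::setNames(as.vector(counts) / (length(chars) - 1), pairs)
}

aa_group_of <- function(chars, groups = AA_GROUPS5) {
  lookup <- stats::setNames(
    rep(names(groups), lengths(groups)), unlist(groups)
  )
  unname(lookup[chars])
}

#' Grouped amino-acid composition (GAAC)
#'
#' Composition over the 5 standard physicochemical groups (aliphatic GAVLMI,
#' aromatic FYW, positively charged KRH, negatively charged DE, uncharged
#' STCPNQ).
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 5.
#' @export
encode_gaac <- function(sequence) {
  check_sequence(sequence)
  g <- aa_group_of(seq_chars(sequence))
  counts <- table(factor(g, levels = names(AA_GROUPS5)))
  stats::setNames(as.vector(counts) / length(g), names(AA_GROUPS5))
}

#' Grouped dipeptide composition (GDPC)
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 25.
#' @export
encode_gdpc <- function(sequence) {
  check_sequence(sequence)
  g <- aa_group_of(seq_chars(sequence))
  pairs <- paste0(rep(names(AA_GROUPS5), each = 5), ".", names(AA_GROUPS5))
  if (length(g) < 2L) {
    short_seq_warning("GDPC")
    return(stats::setNames(numeric(25), pairs))
  }
  di <- paste0(g[-length(g)], ".", g[-1])
  counts <- table(factor(di, levels = pairs))
  stats::setNames(as.vector(counts) / (length(g) - 1), pairs)
}

k_spaced_pairs <- function(symbols, levels, kmax, label) {
  L <- length(symbols)
  pair_names <- paste0(rep(levels, each = length(levels)), ".", levels)
  out <- numeric(0)
  for (k in 0:kmax) {
    n_pairs <- L - k - 1L
    block_names <- paste0("k", k, ".", pair_names)
    if (n_pairs < 1L) {
      short_seq_warning(paste0(label, " k=", k, " block"))
      block <- stats::setNames(numeric(length(pair_names)), block_names)
    } else {
      pr <- paste0(symbols[seq_len(n_pairs)], ".",
                   symbols[seq_len(n_pairs) + k + 1L])
      block <- as.vector(table(factor(pr, levels = pair_names))) / n_pairs
      names(block) <- block_names
    }
    out <- c(out, block)
  }
  out
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each gap `k` in `0..kmax`, the frequency of residue pairs separated by
#' `k` intervening positions, normalized by the number of such pairs; each
#' k-block sums to 1 when the sequence is long enough.
#'
#' @inheritParams encode_aac
#' @param kmax Largest gap (default 2, giving 1200 values).
#' @return Named numeric vector of length `400 * (kmax + 1)`.
#' @export
encode_cksaap <- function(sequence, kmax = 2) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  out <- k_spaced_pairs(chars, AA_ALPHABET, kmax, "CKSAAP")
  names(out) <- sub("^(k[0-9]+)\\.(.)\\.(.)$", "\\1.\\2\\3", names(out))
  out
}

#' Composition of k-spaced amino-acid group pairs (CKSAAGP)
#'
#' Group-pair version of CKSAAP over the 5 physicochemical groups; the default
#' gap range 0..5 gives 25 pairs x 6 gaps = 150 values.
#'
#' @inheritParams encode_aac
#' @param kmax Largest gap (default 5).
#' @return Named numeric vector of length `25 * (kmax + 1)`.
#' @export
encode_cksaagp <- function(sequence, kmax = 5) {
  check_sequence(sequence)
  g <- aa_group_of(seq_chars(sequence))
  k_spaced_pairs(g, names(AA_GROUPS5), kmax, "CKSAAGP")
}

standardize_scale <- function(v) {
  (v - mean(v)) / sqrt(mean((v - mean(v))^2))
}

#' Amphiphilic pseudo amino-acid composition (APAAC)
#'
#' Chou's amphiphilic PseAAC: the 20 composition terms plus `lambda`
#' hydrophobicity- and `lambda` hydrophilicity-correlation factors, weighted
#' by `w` and jointly normalized to sum 1.
#'
#' @inheritParams encode_aac
#' @param lambda Correlation order (default 5); requires `L > lambda`.
#' @param w Weight of the sequence-order terms (default 0.05).
#' @return Named numeric vector of length `20 + 2 * lambda`.
#' @export
encode_apaac <- function(sequence, lambda = 5, w = 0.05) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (L <= lambda) {
    stop("APAAC requires sequence length > lambda (", lambda, ")",
         call. = FALSE)
  }
  h1 <- standardize_scale(PSE_HYDROPHOBICITY)[chars]
  h2 <- standardize_scale(PSE_HYDROPHILICITY)[chars]
  tau <- numeric(2 * lambda)
  for (k in seq_len(lambda)) {
    i <- seq_len(L - k)
    tau[2 * k - 1] <- mean(h1[i] * h1[i + k])
    tau[2 * k]     <- mean(h2[i] * h2[i + k])
  }
  f <- as.vector(table(factor(chars, levels = AA_ALPHABET))) / L
  denom <- 1 + w * sum(tau)
  out <- c(f / denom, w * tau / denom)
  names(out) <- c(
    paste0("c.", AA_ALPHABET),
    paste0("tau", rep(seq_len(lambda), each = 2), ".",
           c("hydrophobicity", "hydrophilicity"))
  )
  out
}

#' Pseudo amino-acid composition (PAAC)
#'
#' Chou's type-1 PseAAC with the classical hydrophobicity, hydrophilicity and
#' side-chain-mass property triple.
#'
#' @inheritParams encode_apaac
#' @return Named numeric vector of length `20 + lambda`.
#' @export
encode_paac <- function(sequence, lambda = 5, w = 0.05) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (L <= lambda) {
    stop("PAAC requires sequence length > lambda (", lambda, ")",
         call. = FALSE)
  }
  props <- rbind(
    standardize_scale(PSE_HYDROPHOBICITY)[chars],
    standardize_scale(PSE_HYDROPHILICITY)[chars],
    standardize_scale(PSE_SIDECHAIN_MASS)[chars]
  )
  theta <- vapply(seq_len(lambda), function(k) {
    i <- seq_len(L - k)
    mean(colMeans((props[, i, drop = FALSE] - props[, i + k, drop = FALSE])^2))
  }, numeric(1))
  f <- as.vector(table(factor(chars, levels = AA_ALPHABET))) / L
  denom <- 1 + w * sum(theta)
  out <- c(f / denom, w * theta / denom)
  names(out) <- c(paste0("c.", AA_ALPHABET), paste0("theta", seq_len(lambda)))
  out
}

#' Shannon entropy of the residue composition (SEP / SER)
#'
#' `encode_sep()` returns the Shannon entropy (base 2) of the 20-residue
#' composition; `encode_ser()` returns the 20 per-residue contributions
#' `-p_a log2 p_a` (0 for absent residues), which sum to the SEP value.
#'
#' @inheritParams encode_aac
#' @return `encode_sep()`: length-1 named vector; `encode_ser()`: length-20.
#' @export
encode_sep <- function(sequence) {
  c(H = sum(encode_ser(sequence)))
}

#' @rdname encode_sep
#' @export
encode_ser <- function(sequence) {
  p <- encode_aac(sequence)
  out <- ifelse(p > 0, -p * log2(p), 0)
  names(out) <- AA_ALPHABET
  out
}

#' Dipeptide deviation from expected mean (DDE)
#'
#' Standardized deviation of each observed dipeptide frequency from its
#' expectation under standard-genetic-code codon usage:
#' `DDE(ab) = (Dc(ab) - Tm(ab)) / sqrt(Tv(ab))` with
#' `Tm(ab) = (Ca/61)(Cb/61)` and `Tv(ab) = Tm(1 - Tm)/(L - 1)`.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400.
#' @export
encode_dde <- function(sequence) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (L < 2L) stop("DDE requires sequence length >= 2", call. = FALSE)
  dc <- encode_dpc(sequence)
  # outer() varies its first argument fastest; DPC names vary the second
  # letter fastest, so transpose to match.
  tm <- as.vector(t(outer(CODON_COUNTS[AA_ALPHABET] / 61,
                          CODON_COUNTS[AA_ALPHABET] / 61)))
  tv <- tm * (1 - tm) / (L - 1)
  stats::setNames((dc - tm) / sqrt(tv), names(dc))
}

#' Conjoint triad descriptor (CTriad)
#'
#' Residues are mapped to the standard 7 conjoint classes and the 343 class
#' triads are counted over all windows of length 3, then min-max normalized
#' (`(f - min(f)) / max(f)`). Sequences shorter than 3 residues yield an
#' all-zero vector with a warning.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 343 with values in `[0, 1]`.
#' @export
encode_ctriad <- function(sequence) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  cls <- aa_group_of(chars, CTRIAD_CLASSES)
  lv <- names(CTRIAD_CLASSES)
  triads <- as.vector(outer(outer(lv, lv, paste, sep = "."), lv, paste, sep = "."))
  triads <- sort(triads)
  if (length(chars) < 3L) {
    short_seq_warning("CTriad")
    return(stats::setNames(numeric(343), triads))
  }
  L <- length(cls)
  tri <- paste(cls[1:(L - 2)], cls[2:(L - 1)], cls[3:L], sep = ".")
  f <- as.vector(table(factor(tri, levels = triads)))
  out <- if (max(f) > 0) (f - min(f)) / max(f) else f
  stats::setNames(out, triads)
}

ctd_group_index <- function(chars, prop) {
  sets <- lapply(CTD_GROUPS[[prop]], function(s) strsplit(s, "")[[1]])
  ifelse(chars %in% sets$g1, 1L, ifelse(chars %in% sets$g2, 2L, 3L))
}

#' Composition-Transition-Distribution descriptors (CTD)
#'
#' Standard 13-property / 3-group CTD. `encode_ctdc()` gives per-property
#' group compositions (39 values); `encode_ctdt()` the frequencies of
#' transitions between distinct groups among adjacent residues (39 values);
#' `encode_ctdd()` the positions (as percent of sequence length) at which the
#' first, 25%, 50%, 75% and 100% occurrence of each group is reached
#' (195 values; 0 for absent groups).
#'
#' @inheritParams encode_aac
#' @return Named numeric vectors of length 39, 39 and 195 respectively.
#' @export
encode_ctdc <- function(sequence) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  out <- lapply(names(CTD_GROUPS), function(prop) {
    g <- ctd_group_index(chars, prop)
    v <- tabulate(g, 3L) / length(g)
    stats::setNames(v, paste0(prop, ".g", 1:3))
  })
  unlist(out)
}

#' @rdname encode_ctdc
#' @export
encode_ctdt <- function(sequence) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  L <- length(chars)
  out <- lapply(names(CTD_GROUPS), function(prop) {
    nm <- paste0(prop, ".t", c("12", "13", "23"))
    if (L < 2L) {
      short_seq_warning(paste0("CTDT ", prop))
      return(stats::setNames(numeric(3), nm))
    }
    g <- ctd_group_index(chars, prop)
    a <- g[-L]; b <- g[-1]
    lo <- pmin(a, b); hi <- pmax(a, b)
    v <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
           sum(lo == 2 & hi == 3)) / (L - 1)
    stats::setNames(v, nm)
  })
  unlist(out)
}

#' @rdname encode_ctdc
#' @export
encode_ctdd <- function(sequence) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  L <- length(chars)
  qs <- c(first = 0, q25 = 0.25, q50 = 0.5, q75 = 0.75, q100 = 1)
  out <- lapply(names(CTD_GROUPS), function(prop) {
    g <- ctd_group_index(chars, prop)
    v <- unlist(lapply(1:3, function(grp) {
      pos <- which(g == grp)
      if (!length(pos)) return(numeric(5))
      idx <- pmax(1L, ceiling(qs * length(pos)))
      pos[idx] / L * 100
    }))
    stats::setNames(v, paste0(prop, ".g", rep(1:3, each = 5), ".", names(qs)))
  })
  unlist(out)
}

#' Distance distribution of residues (DDR)
#'
#' For each residue type, the mean gap between consecutive occurrences,
#' normalized by sequence length; residue types that are absent or occur only
#' once get the sentinel value 0.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 20.
#' @export
encode_ddr <- function(sequence) {
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  L <- length(chars)
  out <- vapply(AA_ALPHABET, function(a) {
    pos <- which(chars == a)
    if (length(pos) < 2L) 0 else mean(diff(pos)) / L
  }, numeric(1))
  stats::setNames(out, AA_ALPHABET)
}

#' Peptide length descriptor
#'
#' @inheritParams encode_aac
#' @return Length-1 named numeric vector.
#' @export
encode_length <- function(sequence) {
  check_sequence(sequence)
  c(L = nchar(sequence))
}

#' Physicochemical-scale autocovariance descriptor
#'
#' Maps the sequence onto a multi-dimensional per-residue scale table
#' (columns z-standardized over the 20 residues) and aggregates each dimension
#' by lagged autocovariance: `AC(d, l) = mean_i x_d(i) x_d(i + l)` for lags
#' `1..max(lags)`. Lags that exceed the sequence length are 0 with a warning.
#'
#' @inheritParams encode_aac
#' @param scale One of `"Ez"`, `"Z3"`, `"Z5"`, `"Cougar"`, `"ABHPRK"`, or a
#'   numeric 20-row matrix with named columns.
#' @param lags Integer vector of lags; defaults per scale give the registry
#'   sizes Ez 30, Z3 30, Z5 75, Cougar 30, ABHPRK 105.
#' @return Named numeric vector of length `ncol(scale) * length(lags)`.
#' @export
encode_scale_descriptor <- function(sequence, scale, lags = NULL) {
  check_sequence(sequence)
  if (is.character(scale)) {
    tab <- switch(scale,
      Ez = EZ_SCALE, Z3 = Z3_SCALE, Z5 = Z5_SCALE,
      Cougar = COUGAR_SCALE, ABHPRK = ABHPRK_SCALE,
      stop("unknown scale table: ", scale, call. = FALSE)
    )
    if (is.null(lags)) {
      lags <- switch(scale, Z5 = 1:15, ABHPRK = 1:15, 1:10)
    }
  } else {
    tab <- scale
    if (is.null(lags)) lags <- 1:10
  }
  chars <- seq_chars(sequence)
  L <- length(chars)
  std <- apply(tab, 2, function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) v * 0 else (v - mean(v)) / s
  })
  rownames(std) <- rownames(tab)
  x <- std[chars, , drop = FALSE]
  out <- numeric(0)
  warned <- FALSE
  for (d in colnames(tab)) {
    for (l in lags) {
      nm <- paste0(d, ".lag", l)
      if (l >= L) {
        if (!warned) { short_seq_warning("scale-descriptor lag terms"); warned <- TRUE }
        out[nm] <- 0
      } else {
        i <- seq_len(L - l)
        out[nm] <- mean(x[i, d] * x[i + l, d])
      }
    }
  }
  out
}

#' Single-property AAindex autocorrelation descriptor
#'
#' Maps the sequence onto one z-standardized AAindex property and summarizes
#' it with the profile mean and standard deviation plus Moreau-Broto, Moran
#' and Geary autocorrelations at lags 1..10 (32 values). Uncomputable terms
#' (lag beyond length, zero profile variance) are 0.
#'
#' @inheritParams encode_aac
#' @param accession AAindex accession string.
#' @param lags Integer lags (default 1..10).
#' @return Named numeric vector of length `2 + 3 * length(lags)`.
#' @export
encode_aaindex_descriptor <- function(sequence, accession, lags = 1:10) {
  check_sequence(sequence)
  v <- standardize_scale(aaindex_scale(accession))
  x <- v[seq_chars(sequence)]
  L <- length(x)
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  out <- c(mean = xbar, sd = if (L > 1) stats::sd(x) else 0)
  warned <- FALSE
  for (l in lags) {
    if (l >= L) {
      if (!warned) { short_seq_warning("AAindex lag terms"); warned <- TRUE }
      mb <- moran <- geary <- 0
    } else {
      i <- seq_len(L - l)
      mb <- mean(x[i] * x[i + l])
      moran <- if (ss == 0) 0 else
        mean((x[i] - xbar) * (x[i + l] - xbar)) / (ss / L)
      geary <- if (ss == 0 || L < 2) 0 else
        (sum((x[i] - x[i + l])^2) / (2 * (L - l))) / (ss / (L - 1))
    }
    out[paste0("MB.lag", l)] <- mb
    out[paste0("Moran.lag", l)] <- moran
    out[paste0("Geary.lag", l)] <- geary
  }
  out
}
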