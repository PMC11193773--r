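test_that("default registry matches the declared encoding envelope", {
  reg <- default_registry()
  expect_equal(nrow(reg), 58L)
  expect_equal(sum(reg$size), 4335L)
  sizes <- stats::setNames(reg$size, reg$type)
  expect_equal(unname(sizes[c("CKSAAGP", "Z5", "Cougar", "Ez", "Z3",
                              "CTDC", "ABHPRK")]),
               c(150L, 75L, 30L, 30L, 30L, 39L, 105L))
  expect_equal(unname(sizes[c("AAC", "DPC", "GAAC", "GDPC", "CTriad",
                              "DDE", "CTDT", "CTDD", "length", "SEP",
                              "SER")]),
               c(20L, 400L, 5L, 25L, 343L, 400L, 39L, 195L, 1L, 1L, 20L))
  expect_false(anyDuplicated(reg$type) > 0)
})

test_that("composition encoders match direct counting", {
  expect_equal(unname(encode_aac("AAAA")["A"]), 1.0)
  expect_equal(sum(encode_aac("AAAA")), 1.0)
  a <- encode_aac("ACDC")
  expect_equal(unname(a[c("A", "C", "D")]), c(0.25, 0.5, 0.25))

  d <- encode_dpc("AAA")
  expect_equal(unname(d["AA"]), 1.0)
  d2 <- encode_dpc("ACAC")
  expect_equal(unname(d2[c("AC", "CA")]), c(2 / 3, 1 / 3))

  g <- encode_gaac("GAVLMI")
  expect_equal(unname(g["aliphatic"]), 1.0)
  gd <- encode_gdpc("KD")
  expect_equal(unname(gd["positive.negative"]), 1.0)
})

test_that("composition encoders sum to 1 and agree with a counting oracle", {
  for (s in random_peptides(20, seed = 11)) {
    expect_equal(sum(encode_aac(s)), 1, tolerance = 1e-12)
    expect_equal(sum(encode_dpc(s)), 1, tolerance = 1e-12)
    expect_equal(sum(encode_gaac(s)), 1, tolerance = 1e-12)
    expect_equal(sum(encode_gdpc(s)), 1, tolerance = 1e-12)
    expect_true(all(encode_aac(s) >= 0))
    # oracle: adjacent-pair counting equals the k=0 spaced-pair matrix
    o <- oracle_kspaced(s, 0)
    dp <- encode_dpc(s)
    expect_equal(unname(dp[paste0(rownames(o)[row(o)], colnames(o)[col(o)])]),
                 unname(as.vector(o)), tolerance = 1e-12)
  }
})

test_that("CKSAAP blocks normalize per gap and match the oracle", {
  v <- encode_cksaap("AA", kmax = 0)
  expect_equal(unname(v["k0.AA"]), 1.0)
  v1 <- encode_cksaap("ACA", kmax = 1)
  expect_equal(unname(v1["k1.AA"]), 1.0)
  for (s in random_peptides(10, min_len = 6, seed = 12)) {
    enc <- encode_cksaap(s, kmax = 2)
    for (k in 0:2) {
      block <- enc[startsWith(names(enc), paste0("k", k, "."))]
      expect_equal(sum(block), 1, tolerance = 1e-12)
      o <- oracle_kspaced(s, k)
      expect_equal(unname(block[paste0("k", k, ".",
                                       rownames(o)[row(o)],
                                       colnames(o)[col(o)])]),
                   unname(as.vector(o)), tolerance = 1e-12)
    }
  }
})

test_that("CKSAAGP is the group-pair analogue with 150 default values", {
  v <- encode_cksaagp("ACDEFGHIKLMNPQRS")
  expect_length(v, 150L)
  v0 <- encode_cksaagp("AA", kmax = 0)
  expect_equal(unname(v0["k0.aliphatic.aliphatic"]), 1.0)
  s <- "ACDEFGHIKLMNPQRSTVWY"
  enc <- encode_cksaagp(s, kmax = 5)
  for (k in 0:5) {
    expect_equal(sum(enc[startsWith(names(enc), paste0("k", k, "."))]), 1,
                 tolerance = 1e-12)
  }
})

test_that("short sequences zero-fill spaced-pair blocks with a warning", {
  expect_warning(v <- encode_cksaap("AC", kmax = 2), "too short")
  expect_equal(sum(v[startsWith(names(v), "k1.")]), 0)
  expect_equal(sum(v[startsWith(names(v), "k0.")]), 1)
  expect_warning(v1 <- encode_dpc("A"), "too short")
  expect_equal(sum(v1), 0)
})

test_that("APAAC matches a step-by-step evaluation of the formulas", {
  # independent oracle on a 5-mer, lambda = 2
  s <- "ACDWA"
  lam <- 2; w <- 0.05
  chars <- strsplit(s, "")[[1]]
  std <- function(h) (h - mean(h)) / sqrt(mean((h - mean(h))^2))
  h1 <- std(PSE_HYDROPHOBICITY)[chars]
  h2 <- std(PSE_HYDROPHILICITY)[chars]
  tau <- c()
  for (k in 1:lam) {
    i <- 1:(5 - k)
    tau <- c(tau, mean(h1[i] * h1[i + k]), mean(h2[i] * h2[i + k]))
  }
  f <- table(factor(chars, levels = AA_ALPHABET)) / 5
  expected <- c(as.numeric(f), w * tau) / (1 + w * sum(tau))
  got <- encode_apaac(s, lambda = lam, w = w)
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  expect_length(encode_apaac("ACDEFG", lambda = 3), 26L)

  # homopolymer: correlation terms are exact squares of the standardized value
  hp <- encode_apaac("AAAAA", lambda = 1)
  tau_a <- c(std(PSE_HYDROPHOBICITY)["A"]^2, std(PSE_HYDROPHILICITY)["A"]^2)
  denom <- 1 + 0.05 * sum(tau_a)
  expect_equal(unname(hp["c.A"]), 1 / denom, tolerance = 1e-12)
  expect_equal(unname(hp[21:22]), unname(0.05 * tau_a / denom),
               tolerance = 1e-12)

  expect_error(encode_apaac("ACD", lambda = 5), "lambda")
})

test_that("PAAC output sums to 1 and has length 20 + lambda", {
  v <- encode_paac("ACDEFGHIKL", lambda = 5)
  expect_length(v, 25L)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_error(encode_paac("ACD", lambda = 5), "lambda")
})

test_that("Shannon entropy encoders satisfy their closed forms", {
  expect_equal(unname(encode_sep("AAAA")), 0)
  all20 <- paste(AA_ALPHABET, collapse = "")
  expect_equal(unname(encode_sep(all20)), log2(20), tolerance = 1e-12)
  for (s in random_peptides(10, seed = 13)) {
    expect_equal(unname(encode_sep(s)), sum(encode_ser(s)),
                 tolerance = 1e-12)
  }
})

test_that("DDE matches direct arithmetic with the codon table", {
  v <- encode_dde("AA")
  tm <- (4 / 61)^2
  tv <- tm * (1 - tm) / 1
  expect_equal(unname(v["AA"]), (1 - tm) / sqrt(tv), tolerance = 1e-12)
  # absent dipeptide with positive expectation is negative
  expect_true(v["CC"] < 0)
  expect_length(v, 400L)
  # independent spot-check on a longer peptide
  s <- "ACDAC"
  v2 <- encode_dde(s)
  dc_ac <- 2 / 4
  tm_ac <- (4 / 61) * (2 / 61)
  tv_ac <- tm_ac * (1 - tm_ac) / 4
  expect_equal(unname(v2["AC"]), (dc_ac - tm_ac) / sqrt(tv_ac),
               tolerance = 1e-12)
  expect_error(encode_dde("A"), "length")
})

test_that("conjoint triad output is min-max normalized over 343 classes", {
  v <- encode_ctriad("AAA")
  expect_length(v, 343L)
  expect_equal(unname(v["g1.g1.g1"]), 1.0)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(unname(which.max(v)), which(names(v) == "g1.g1.g1"))
  expect_warning(v2 <- encode_ctriad("AC"), "too short")
  expect_equal(sum(v2), 0)
})

test_that("CTD encoders respect the 13-property partition", {
  # every property's groups partition the alphabet
  for (g in CTD_GROUPS) {
    ch <- unlist(strsplit(unlist(g), ""))
    expect_length(ch, 20L)
    expect_setequal(ch, AA_ALPHABET)
  }
  c_ <- encode_ctdc("AAAA")
  expect_length(c_, 39L)
  # per-property composition sums to 1
  for (prop in names(CTD_GROUPS)) {
    expect_equal(sum(c_[startsWith(names(c_), paste0(prop, "."))]), 1,
                 tolerance = 1e-12)
  }
  # homopolymer: the group containing A has composition 1, transitions 0
  t_ <- encode_ctdt("AAAA")
  expect_length(t_, 39L)
  expect_true(all(t_ == 0))
  d_ <- encode_ctdd("AAAA")
  expect_length(d_, 195L)
  # for property "charge", A is in group 2: distribution of g2 is
  # 1/4, 1/4, 2/4, 3/4, 4/4 of the length (x100)
  expect_equal(unname(d_[paste0("charge.g2.",
                                c("first", "q25", "q50", "q75", "q100"))]),
               c(25, 25, 50, 75, 100))
  expect_equal(sum(d_[startsWith(names(d_), "charge.g1")]), 0)
})

test_that("DDR reflects occurrence gaps with a 0 sentinel", {
  # A at positions 1 and 3 in a 4-mer: single gap of 2, normalized by L
  v <- encode_ddr("ACAD")
  expect_equal(unname(v["A"]), 2 / 4)
  expect_equal(unname(v["C"]), 0)  # singleton
  expect_equal(unname(v["W"]), 0)  # absent
  # homopolymer: all gaps 1/L
  expect_equal(unname(encode_ddr("AAAAA")["A"]), 1 / 5)
  # oracle via explicit positions
  s <- "WAWAWWA"
  pos <- which(strsplit(s, "")[[1]] == "W")
  expect_equal(unname(encode_ddr(s)["W"]), mean(diff(pos)) / nchar(s))
})

test_that("scale descriptors have pinned sizes and homopolymer closed form", {
  expect_length(encode_scale_descriptor("ACDEFGHIKLMNPQRSTVW", "Z5"), 75L)
  expect_length(encode_scale_descriptor("ACDEFGHIKLMNPQRSTVW", "ABHPRK"), 105L)
  expect_length(encode_scale_descriptor("ACDEFGHIKLMNPQRSTVW", "Ez"), 30L)
  expect_length(encode_scale_descriptor("ACDEFGHIKLMNPQRSTVW", "Cougar"), 30L)
  expect_length(encode_scale_descriptor("ACDEFGHIKLMNPQRSTVW", "Z3"), 30L)
  # homopolymer 6-mer: every lag term is the square of the standardized value
  v <- encode_scale_descriptor("AAAAAA", "Z3", lags = 1:3)
  std <- apply(Z3_SCALE, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  expect_equal(unname(v), unname(rep(std["A", ], each = 3)^2),
               tolerance = 1e-12)
  # lags beyond the sequence length are zero with a warning
  expect_warning(v2 <- encode_scale_descriptor("ACD", "Z5"), "too short")
  expect_true(all(v2[grepl("lag1[0-5]$", names(v2))] == 0))
})

test_that("AAindex descriptors compute standard autocorrelations", {
  v <- encode_aaindex_descriptor("ACDEFGHIKL", "HOPT810101")
  expect_length(v, 32L)
  # homopolymer: Moran/Geary undefined (zero variance) -> 0 sentinel;
  # Moreau-Broto equals the squared standardized value
  h <- encode_aaindex_descriptor("CCCCC", "HOPT810101")
  std <- local({
    x <- aaindex_scale("HOPT810101")
    (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  })
  expect_equal(unname(h["MB.lag1"]), unname(std["C"]^2), tolerance = 1e-12)
  expect_equal(unname(h["Moran.lag1"]), 0)
  expect_equal(unname(h["sd"]), 0)
  # independent Moran oracle on a short peptide
  s <- "ACWD"
  x <- std <- NULL
  x <- local({
    v0 <- aaindex_scale("HOPT810101")
    ((v0 - mean(v0)) / sqrt(mean((v0 - mean(v0))^2)))[strsplit(s, "")[[1]]]
  })
  xbar <- mean(x)
  moran1 <- mean((x[1:3] - xbar) * (x[2:4] - xbar)) /
    (sum((x - xbar)^2) / 4)
  got <- encode_aaindex_descriptor(s, "HOPT810101")
  expect_equal(unname(got["Moran.lag1"]), moran1, tolerance = 1e-12)
})

test_that("encode_peptides builds a rectangular deterministic matrix", {
  ds <- tiny_dataset()
  reg <- registry_subset(default_registry(), c("AAC", "DPC", "length"))
  m <- encode_peptides(ds, reg)
  expect_equal(nrow(m), 5L)
  expect_length(feature_names(m), 421L)
  expect_false(anyDuplicated(names(m)) > 0)
  expect_false(any(is.na(m[, feature_names(m)])))
  expect_true(all(startsWith(feature_names(m),
                             c("length.", "AAC.", "DPC."))[1]))
  # determinism
  m2 <- encode_peptides(ds, reg)
  expect_identical(m, m2)
  # permuting rows permutes the matrix identically
  perm <- c(3, 1, 5, 2, 4)
  m3 <- encode_peptides(ds[perm, ], reg)
  expect_equal(as.data.frame(m3), as.data.frame(m[perm, ]),
               ignore_attr = TRUE)
  # error carries the sample id
  bad <- tibble::tibble(id = "short", sequence = "ACD", label = 1L)
  expect_error(
    encode_peptides(bad, registry_subset(default_registry(), "APAAC")),
    "short"
  )
})

test_that("full registry encodes to 4335 columns with stable names", {
  ds <- tiny_dataset()
  m <- suppressWarnings(encode_peptides(ds))
  expect_length(feature_names(m), 4335L)
  expect_false(any(is.na(m[, feature_names(m)])))
  expect_equal(m$label, ds$label)
  expect_true(nzchar(attr(m, "registry_hash")))
})

test_that("feature matrices round-trip through CSV", {
  ds <- tiny_dataset()
  reg <- registry_subset(default_registry(), c("AAC", "SEP"))
  m <- encode_peptides(ds, reg)
  tf <- tempfile(fileext = ".csv")
  write_feature_matrix(m, tf)
  back <- read_feature_matrix(tf)
  expect_equal(as.data.frame(back), as.data.frame(m), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("registry manifest records every spec", {
  tf <- tempfile(fileext = ".json")
  write_registry_manifest(default_registry(), tf)
  man <- jsonlite::read_json(tf)
  expect_equal(man$n_types, 58L)
  expect_equal(man$n_values, 4335L)
  expect_length(man$specs, 58L)
})
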