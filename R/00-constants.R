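# Residue alphabets, group schemes and physicochemical scale tables used by the
# descriptor registry. All tables are keyed by the canonical 20-letter alphabet
# in the fixed order below; that order is the tie-break and naming order
# everywhere in the package.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Five-group physicochemical scheme used by GAAC/GDPC/CKSAAGP.
AA_GROUPS5 <- list(
  aliphatic = c("G", "A", "V", "L", "M", "I"),
  aromatic  = c("F", "Y", "W"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  uncharged = c("S", "T", "C", "P", "N", "Q")
)

# Seven conjoint-triad classes (dipole / side-chain volume clustering).
CTRIAD_CLASSES <- list(
  g1 = c("A", "G", "V"),
  g2 = c("I", "L", "F", "P"),
  g3 = c("Y", "M", "T", "S"),
  g4 = c("H", "N", "Q", "W"),
  g5 = c("R", "K"),
  g6 = c("D", "E"),
  g7 = c("C")
)

# Standard-genetic-code codon counts per residue (sum = 61), for DDE.
CODON_COUNTS <- c(
  A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3, K = 2, L = 6,
  M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6, T = 4, V = 4, W = 1, Y = 2
)

# 13-property / 3-group partition for the CTD descriptors. Each property's
# three groups partition the 20-letter alphabet (asserted in tests).
CTD_GROUPS <- list(
  hydrophobicity_PRAM900101 = list(g1 = "RKEDQN",     g2 = "GASTPHY",          g3 = "CLVIMFW"),
  hydrophobicity_ARGP820101 = list(g1 = "QSTNGDE",    g2 = "RAHCKMV",          g3 = "LYPFIW"),
  hydrophobicity_ZIMJ680101 = list(g1 = "QNGSWTDERA", g2 = "HMCKV",            g3 = "LPFYI"),
  hydrophobicity_PONP930101 = list(g1 = "KPDESNQT",   g2 = "GRHA",             g3 = "YMFWLCVI"),
  hydrophobicity_CASG920101 = list(g1 = "KDEQPSRNTG", g2 = "AHYMLV",           g3 = "FIWC"),
  hydrophobicity_ENGD860101 = list(g1 = "RDKENQHYP",  g2 = "SGTAW",            g3 = "CVLIMF"),
  hydrophobicity_FASG890101 = list(g1 = "KERSQD",     g2 = "NTPG",             g3 = "AYHWVMFLIC"),
  normwaalsvolume           = list(g1 = "GASTPDC",    g2 = "NVEQIL",           g3 = "MHKFRYW"),
  polarity                  = list(g1 = "LIFWCMVY",   g2 = "PATGS",            g3 = "HQRKNED"),
  polarizability            = list(g1 = "GASDT",      g2 = "CPNVEQIL",         g3 = "KMHFRYW"),
  charge                    = list(g1 = "KR",         g2 = "ANCQGHILMFPSTWYV", g3 = "DE"),
  secondarystruct           = list(g1 = "EALMQKRH",   g2 = "VIYCWFT",          g3 = "GNPSD"),
  solventaccess             = list(g1 = "ALFCGIVW",   g2 = "RKQEND",           g3 = "MSPTHY")
)

# Hydrophobicity / hydrophilicity / side-chain mass tables for the pseudo
# amino-acid composition descriptors (Tanford-type hydrophobicity, Hopp-Woods
# hydrophilicity, side-chain masses in Da).
PSE_HYDROPHOBICITY <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48, H = -0.40,
  I =  1.38, K = -1.50, L =  1.06, M =  0.64, N = -0.78, P = 0.12, Q = -0.85,
  R = -2.53, S = -0.18, T = -0.05, V =  1.08, W = 0.81, Y = 0.26
)
PSE_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5, G =  0.0, H = -0.5,
  I = -1.8, K =  3.0, L = -1.8, M = -1.3, N =  0.2, P =  0.0, Q =  0.2,
  R =  3.0, S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3
)
PSE_SIDECHAIN_MASS <- c(
  A =  15.0, C =  47.0, D =  59.0, E =  73.0, F =  91.0, G =   1.0, H = 82.0,
  I =  57.0, K =  73.0, L =  57.0, M =  75.0, N =  58.0, P =  42.0, Q = 72.0,
  R = 101.0, S =  31.0, T =  45.0, V =  43.0, W = 130.0, Y = 107.0
)

aa_scale_matrix <- function(values_by_dim, dim_names) {
  m <- do.call(cbind, values_by_dim)
  rownames(m) <- AA_ALPHABET
  colnames(m) <- dim_names
  m
}

# Five-dimensional z-scales (Sandberg et al. 1998): hydrophobicity, steric
# bulk/polarizability, polarity, electronic effects (two axes). The Z3
# descriptor uses the first three axes.
Z5_SCALE <- local({
  tab <- rbind(
    A = c( 0.24, -2.32,  0.60, -0.14,  1.30),
    C = c( 0.84, -1.67,  3.71,  0.18, -2.65),
    D = c( 3.98,  0.93,  1.93, -2.46,  0.75),
    E = c( 3.11,  0.26, -0.11, -3.04, -0.25),
    F = c(-4.22,  1.94,  1.06,  0.54, -0.62),
    G = c( 2.05, -4.06,  0.36, -0.82, -0.38),
    H = c( 2.47,  1.95,  0.26,  3.90,  0.09),
    I = c(-3.89, -1.73, -1.71, -0.84,  0.26),
    K = c( 2.29,  0.89, -2.49,  1.49,  0.31),
    L = c(-4.28, -1.30, -1.49, -0.72,  0.84),
    M = c(-2.85, -0.22,  0.47,  1.94, -0.98),
    N = c( 3.05,  1.62,  1.04, -1.15,  1.61),
    P = c(-1.66,  0.27,  1.84,  0.70,  2.00),
    Q = c( 1.75,  0.50, -1.44, -1.34,  0.66),
    R = c( 3.52,  2.50, -3.50,  1.99, -0.17),
    S = c( 2.39, -1.07,  1.15, -1.39,  0.67),
    T = c( 0.75, -2.18, -1.12, -1.46, -0.40),
    V = c(-2.59, -2.64, -1.54, -0.85, -0.02),
    W = c(-4.36,  3.94,  0.59,  3.44, -1.59),
    Y = c(-2.54,  2.44,  0.43,  0.04, -1.47)
  )
  colnames(tab) <- paste0("z", 1:5)
  tab[AA_ALPHABET, , drop = FALSE]
})

Z3_SCALE <- Z5_SCALE[, 1:3, drop = FALSE]

# Depth-dependent membrane-insertion pseudo-energy parameters (Senes et al.
# 2007 Ez potential): per residue, the energy amplitude E0, the midpoint/peak
# depth zm (Angstrom) and the steepness/width parameter n.
EZ_SCALE <- local({
  tab <- rbind(
    A = c(-0.29, 10.22,  4.67),
    C = c( 0.95, 13.69,  5.77),
    D = c( 1.19, 14.25,  8.98),
    E = c( 1.30, 14.66,  4.16),
    F = c(-0.80, 19.67,  7.12),
    G = c(-0.01, 13.86,  6.00),
    H = c( 0.75, 12.26,  2.77),
    I = c(-0.56, 14.34, 10.69),
    K = c( 1.66, 11.11,  2.09),
    L = c(-0.64, 17.34,  8.61),
    M = c(-0.28, 18.04,  7.13),
    N = c( 0.89, 12.78,  6.28),
    P = c( 0.83, 18.09,  3.53),
    Q = c( 0.97, 10.46,  2.59),
    R = c( 0.91,  9.34,  4.68),
    S = c( 0.10, 13.86,  6.00),
    T = c( 0.01, 13.86,  6.00),
    V = c(-0.47, 11.35,  4.97),
    W = c(-0.85, 11.65,  7.20),
    Y = c(-0.42, 13.04,  6.20)
  )
  colnames(tab) <- c("E0", "zm", "n")
  tab[AA_ALPHABET, , drop = FALSE]
})

# Composite three-axis scale: Kyte-Doolittle hydropathy, side-chain net charge
# at pH 7 (His counted 0.5), side-chain volume (Angstrom^3, Zamyatnin).
COUGAR_SCALE <- local({
  kd <- c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8, G = -0.4,
          H = -3.2, I =  4.5, K = -3.9, L =  3.8, M =  1.9, N = -3.5,
          P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V =  4.2,
          W = -0.9, Y = -1.3)
  chg <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.5, I = 0,
           K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
           T = 0, V = 0, W = 0, Y = 0)
  vol <- c(A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
           G =  60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
           M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
           S =  89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6)
  aa_scale_matrix(list(kd[AA_ALPHABET], chg[AA_ALPHABET], vol[AA_ALPHABET]),
                  c("hydropathy", "charge", "volume"))
})

# Seven binary property indicator axes: Acidic, Basic, Hydrophobic, Polar,
# aRomatic, Kink-inducing, aLiphatic.
ABHPRK_SCALE <- local({
  ind <- function(set) as.numeric(AA_ALPHABET %in% strsplit(set, "")[[1]])
  aa_scale_matrix(
    list(ind("DE"), ind("KRH"), ind("VILMFWC"), ind("STNQY"),
         ind("FYWH"), ind("PG"), ind("AVLI")),
    c("acidic", "basic", "hydrophobic", "polar", "aromatic", "kink", "aliphatic")
  )
})

# AAindex accessions backing the 36 single-property autocorrelation
# descriptors (tables loaded from seqinr's bundled aaindex data at run time).
AAINDEX_SET <- c(
  "HOPT810101", "EISD840101", "JANJ780101", "GRAR740102", "ZIMJ680102",
  "ZIMJ680104", "ZIMJ680105", "CHOC760101", "CHAM820101", "FAUJ880103",
  "FASG760101", "BHAR880101", "CHAM830107", "CHOP780201", "CHOP780202",
  "CHOP780203", "GUYH850101", "JOND750101", "KRIW790101", "LEVM760101",
  "MANP780101", "MAXF760101", "MEEJ800101", "NAKH900109", "NOZY710101",
  "OOBM770101", "PONP800101", "RACS770103", "RADA880108", "ROBB760107",
  "ROSG850101", "SIMZ760101", "VINM940101", "WERD780101", "WOEC730101",
  "DAWD720101"
)

# Residue sets for the property-stratified accuracy analysis.
PROPERTY_SETS <- list(
  hydrophobic = c("V", "I", "L", "M", "F", "W", "C"),
  hydrophilic = c("R", "N", "D", "E", "Q", "H", "K", "S", "T"),
  charged     = c("E", "D", "R", "K", "H")
)

.aaindex_cache <- new.env(parent = emptyenv())

# Three-letter to one-letter residue mapping used when reading aaindex tables.
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

#' Retrieve a per-residue AAindex scale
#'
#' Loads one AAindex property table (via the aaindex data bundled with
#' seqinr) as a numeric vector over the 20 canonical residues in alphabet
#' order. Tables are cached for the session.
#'
#' @param accession AAindex accession string, e.g. `"HOPT810101"`.
#' @return Named numeric vector of length 20.
#' @keywords internal
aaindex_scale <- function(accession) {
  if (!exists(accession, envir = .aaindex_cache)) {
    if (!exists("aaindex_db", envir = .aaindex_cache)) {
      env <- new.env()
      utils::data("aaindex", package = "seqinr", envir = env)
      assign("aaindex_db", env$aaindex, envir = .aaindex_cache)
    }
    db <- get("aaindex_db", envir = .aaindex_cache)
    entry <- db[[accession]]
    if (is.null(entry)) {
      stop("unknown AAindex accession: ", accession, call. = FALSE)
    }
    v <- entry$I
    names(v) <- AA_THREE_TO_ONE[names(v)]
    v <- v[AA_ALPHABET]
    if (any(is.na(v))) {
      stop("AAindex table ", accession, " is incomplete", call. = FALSE)
    }
    assign(accession, v, envir = .aaindex_cache)
  }
  get(accession, envir = .aaindex_cache)
}
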