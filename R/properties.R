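# Physicochemical property tables bundled with the package. All tables are
# keyed by the canonical alphabetical residue order (AA_ALPHABET). The three
# pseudo-composition properties are the classic tables used by pseudo
# amino-acid composition descriptors: hydrophobicity (Tanford/Chou scale),
# hydrophilicity (Hopp-Woods), and side-chain mass.

#' Pseudo-composition property tables
#'
#' Named list of three numeric vectors over the 20 canonical residues:
#' `hydrophobicity`, `hydrophilicity` and `mass` (side-chain mass). These
#' drive the sequence-order correlation terms of the pseudo and amphiphilic
#' pseudo amino-acid composition encoders and the default Moran
#' autocorrelation property. Values are the conventional descriptor-toolkit
#' tables; they are standardised (zero mean, unit population variance over
#' the 20 residues) before use.
#'
#' @return Named list of three named numeric vectors.
#' @export
paac_properties <- function() {
  list(
    hydrophobicity = c(
      A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
      G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
      M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
      S = -0.18, T = -0.26, V =  1.08, W =  0.81, Y =  0.26),
    hydrophilicity = c(
      A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
      G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
      M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
      S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
    mass = c(
      A =  15.0, C =  47.0, D =  59.0, E =  73.0, F =  91.0,
      G =   1.0, H =  82.0, I =  57.0, K =  73.0, L =  57.0,
      M =  75.0, N =  58.0, P =  42.0, Q =  72.0, R = 101.0,
      S =  31.0, T =  45.0, V =  43.0, W = 130.0, Y = 107.0)
  )
}

# Standardise a property vector over the 20 residues using the population
# standard deviation (divide by 20), the convention of pseudo-composition
# descriptors.
standardize_property <- function(p) {
  p <- p[AA_ALPHABET]
  (p - mean(p)) / sqrt(mean((p - mean(p))^2))
}

# CTD three-group residue partitions for 13 physicochemical properties
# (seven hydrophobicity scales, normalised van der Waals volume, polarity,
# polarizability, charge, secondary structure, solvent accessibility).
# Each property partitions the 20 residues into exactly three groups.
ctd_groups <- function() {
  g <- list(
    hydrophobicity_PRAM900101 = c("RKEDQN",     "GASTPHY",          "CLVIMFW"),
    hydrophobicity_ARGP820101 = c("QSTNGDE",    "RAHCKMV",          "LYPFIW"),
    hydrophobicity_ZIMJ680101 = c("QNGSWTDERA", "HMCKV",            "LPFYI"),
    hydrophobicity_PONP930101 = c("KPDESNQT",   "GRHA",             "YMFWLCVI"),
    hydrophobicity_CASG920101 = c("KDEQPSRNTG", "AHYMLV",           "FIWC"),
    hydrophobicity_ENGD860101 = c("RDKENQHYP",  "SGTAW",            "CVLIMF"),
    hydrophobicity_FASG890101 = c("KERSQD",     "NTPG",             "AYHWVMFLIC"),
    normwaalsvolume           = c("GASTPDC",    "NVEQIL",           "MHKFRYW"),
    polarity                  = c("LIFWCMVY",   "PATGS",            "HQRKNED"),
    polarizability            = c("GASDT",      "CPNVEQIL",         "KMHFRYW"),
    charge                    = c("KR",         "ANCQGHILMFPSTWYV", "DE"),
    secondarystruct           = c("EALMQKRH",   "VIYCWFT",          "GNPSD"),
    solventaccess             = c("ALFCGIVW",   "RKQEND",           "MSPTHY")
  )
  lapply(g, function(x) lapply(strsplit(x, ""), sort))
}

# Conjoint-triad 7-class residue grouping (dipole / side-chain volume
# clusters): {AGV} {ILFP} {YMTS} {HNQW} {RK} {DE} {C}.
ctriad_classes <- function() {
  list(c("A", "G", "V"),
       c("I", "L", "F", "P"),
       c("Y", "M", "T", "S"),
       c("H", "N", "Q", "W"),
       c("R", "K"),
       c("D", "E"),
       c("C"))
}

#' Reduced amino-acid cluster schemes
#'
#' Returns the named list of residue clusters for a reduced-alphabet
#' composition scheme. The default scheme `"four"` partitions the alphabet
#' into four physicochemical clusters: charged, polar, aromatic or large
#' hydrophobic, and small hydrophobic.
#'
#' @param scheme Scheme identifier; currently `"four"`.
#' @return Named list of character vectors partitioning the 20 residues.
#' @export
raac_scheme <- function(scheme = "four") {
  schemes <- list(
    four = list(
      charged     = c("D", "E", "H", "K", "R"),
      polar       = c("C", "N", "Q", "S", "T"),
      large_hydro = c("F", "I", "L", "M", "V", "W", "Y"),
      small_hydro = c("A", "G", "P")
    )
  )
  if (!scheme %in% names(schemes)) {
    stop("unknown reduced-alphabet scheme: ", scheme)
  }
  cl <- schemes[[scheme]]
  all_res <- sort(unlist(cl, use.names = FALSE))
  if (!identical(all_res, AA_ALPHABET)) {
    stop("scheme '", scheme, "' is not a partition of the 20 residues")
  }
  cl
}
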