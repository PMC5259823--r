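# Packaged constant tables: propensity index, reference scales, patch
# generation thresholds, van der Waals radii.

# Canonical one-letter order used for all 20-key tables.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"  # selenomethionine treated as Met
)

AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

# Quantitative interface propensity index (QIPI): relative interface
# ratio w_i/W_i of each residue type, interface vs non-interface
# surface, from a large non-redundant domain-domain interface set.
QIPI <- c(
  H = 1.147, R = 1.346, K = 0.784, A = 0.841, V = 0.994,
  I = 1.084, L = 1.144, M = 1.451, P = 1.109, F = 1.334,
  W = 1.284, Y = 1.368, G = 0.823, C = 1.172, S = 0.873,
  T = 0.966, N = 0.958, Q = 0.909, D = 0.830, E = 0.805
)[AA20]

# JANJ780101 (AAindex): average accessible surface area (A^2) of each
# residue type in folded proteins; the reference state for the residue
# propensity score.
REF_ASA <- c(
  A = 27.8, R = 94.7, N = 60.1, D = 60.6, C = 15.5,
  Q = 68.7, E = 68.2, G = 24.5, H = 50.7, I = 22.8,
  L = 27.6, K = 103.0, M = 33.5, F = 25.5, P = 51.5,
  S = 42.0, T = 45.0, W = 34.7, Y = 55.2, V = 23.7
)[AA20]

# CASG920101 (AAindex): structure-derived hydrophobic potential
# (Casari-Sippl), used as the per-residue hydrophobic score.
HYDRO <- c(
  A = 0.2, R = -0.7, N = -0.5, D = -1.4, C = 1.9,
  Q = -1.1, E = -1.3, G = -0.1, H = 0.4, I = 1.4,
  L = 0.5, K = -1.6, M = 0.5, F = 1.0, P = -1.0,
  S = -0.7, T = -0.4, W = 1.6, Y = 0.5, V = 0.7
)[AA20]

# BLOSUM62 diagonal (self-substitution scores B_rr).
BLOSUM62_DIAG <- c(
  A = 4, R = 5, N = 6, D = 6, C = 9,
  Q = 5, E = 5, G = 6, H = 8, I = 4,
  L = 4, K = 5, M = 5, F = 6, P = 7,
  S = 4, T = 5, W = 11, Y = 7, V = 4
)[AA20]

# Patch growth: a neighbour at seed distance in (lo, hi] joins the
# patch when its ASA exceeds min_asa; d <= 2 A joins unconditionally,
# d > 15 A never joins.
PATCH_GROWTH <- data.frame(
  lo      = c(2, 5, 7, 9, 11, 13),
  hi      = c(5, 7, 9, 11, 13, 15),
  min_asa = c(0, 20, 40, 60, 80, 100)
)

# Patch merging: minimum identity ratio between two patches, chosen by
# total domain ASA (A^2).
MERGE_THRESHOLDS <- data.frame(
  lo    = c(0, 5000, 7500, 10000),
  hi    = c(5000, 7500, 10000, Inf),
  ratio = c(0.8, 0.7, 0.6, 0.5)
)

# Chothia-style van der Waals radii by element (A); unknown elements
# fall back to 1.80 A.
VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, SE = 1.90, P = 1.90)
VDW_DEFAULT <- 1.80

# Four chemical groups used for the aggregated contact preferences.
GROUP4 <- c(
  H = "basic", R = "basic", K = "basic",
  A = "hydrophobic", V = "hydrophobic", I = "hydrophobic",
  L = "hydrophobic", M = "hydrophobic", P = "hydrophobic",
  F = "hydrophobic", W = "hydrophobic", G = "hydrophobic",
  C = "hydrophobic",
  Y = "polar", S = "polar", T = "polar", N = "polar", Q = "polar",
  D = "acidic", E = "acidic"
)[AA20]
names(GROUP4) <- AA20

# Column order of the PSI-BLAST ASCII PSSM score block.
PSSM_COLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Default scoring weights (w1 hydrophobic, w2 conservation, w3
# solvation), trained on the packaged synthetic-complex generator; see
# the methods vignette. Override per call or via a weights JSON file.
DEFAULT_WEIGHTS <- c(w1 = 0.5, w2 = 2, w3 = 0.25)

#' Packaged constant tables
#'
#' Returns the constant tables used throughout the package: the
#' quantitative interface propensity index (QIPI, the 20 relative
#' interface ratios), the JANJ780101 reference accessible-surface
#' areas, the CASG920101 hydrophobicity potential, the BLOSUM62
#' diagonal, the patch-growth distance/ASA thresholds, the
#' domain-size-dependent patch-merge identity-ratio thresholds, the
#' van der Waals radius set, the four-group residue classification and
#' the default scoring weights.
#'
#' @return A named list with elements `qipi`, `ref_asa`, `hydro`,
#'   `blosum62_diag`, `patch_growth`, `merge_thresholds`, `vdw_radii`,
#'   `vdw_default`, `group4`, `pssm_cols`, `default_weights` and
#'   `aa20`.
#' @examples
#' spr_constants()$qipi["M"]
#' @export
spr_constants <- function() {
  list(
    qipi = QIPI,
    ref_asa = REF_ASA,
    hydro = HYDRO,
    blosum62_diag = BLOSUM62_DIAG,
    patch_growth = PATCH_GROWTH,
    merge_thresholds = MERGE_THRESHOLDS,
    vdw_radii = VDW_RADII,
    vdw_default = VDW_DEFAULT,
    group4 = GROUP4,
    pssm_cols = PSSM_COLS,
    default_weights = DEFAULT_WEIGHTS,
    aa20 = AA20
  )
}

#' Patch-merge identity-ratio threshold for a domain size
#'
#' @param domain_asa Total accessible surface area of the domain (A^2).
#' @return The minimum identity ratio required to merge two patches.
#' @export
merge_threshold <- function(domain_asa) {
  if (!is.numeric(domain_asa) || length(domain_asa) != 1L ||
      !is.finite(domain_asa) || domain_asa <= 0) {
    stop("`domain_asa` must be a single positive number")
  }
  tb <- MERGE_THRESHOLDS
  i <- which(domain_asa > tb$lo & domain_asa <= tb$hi)
  tb$ratio[i]
}
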