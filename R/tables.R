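#' @keywords internal
"_PACKAGE"

## Amino-acid lookup tables used across the package. Kept as plain named
## vectors so every module shares one source of truth.

#' Three-letter to one-letter amino-acid codes
#'
#' Standard 20 residues plus common modified residues that occur in deposited
#' X-ray models (MSE -> M, SEC/CSO -> C, MLY -> K). Anything else maps to "X".
#' @keywords internal
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", CSO = "C", MLY = "K", PTR = "Y",
  SEP = "S", TPO = "T", HYP = "P"
)

AA1 <- sort(unname(AA_3TO1[1:20]))

AA_1TO3 <- stats::setNames(names(AA_3TO1)[1:20], unname(AA_3TO1[1:20]))

#' Van der Waals radii by element (Angstrom)
#'
#' Bondi-style heavy-atom radii used by the SASA sampler; elements not listed
#' fall back to carbon.
#' @keywords internal
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  H = 1.20
)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_RADII[["C"]]
  unname(r)
}

#' Fully-exposed side-chain reference areas (Angstrom^2)
#'
#' Reference solvent-accessible side-chain areas of residue X in an extended
#' tripeptide context, used to normalise observed side-chain SASA to a
#' relative exposure in [0, 1]. Glycine has no heavy side-chain atoms and is
#' assigned a nominal small value so its ratio is defined (and its
#' hydrophobicity weight is zero anyway).
#' @keywords internal
SIDECHAIN_REF_SASA <- c(
  A = 67,  R = 196, N = 113, D = 106, C = 104,
  Q = 144, E = 138, G = 25,  H = 151, I = 140,
  L = 137, K = 167, M = 160, F = 175, P = 105,
  S = 80,  T = 102, W = 217, Y = 187, V = 117
)

#' Black-Mould hydrophobicity, normalised and zero-centred at glycine
#'
#' Polar residues contribute negatively, hydrophobics positively; glycine is
#' exactly zero. This is the weighting used by spatial aggregation propensity
#' scoring.
#' @keywords internal
HYDROPHOBICITY_BM <- c(
  A = 0.616, C = 0.680, D = 0.028, E = 0.043, F = 1.000,
  G = 0.501, H = 0.165, I = 0.943, K = 0.283, L = 0.943,
  M = 0.738, N = 0.236, P = 0.711, Q = 0.251, R = 0.000,
  S = 0.359, T = 0.450, V = 0.825, W = 0.878, Y = 0.880
) - 0.501

## Kyte-Doolittle hydropathy, formal side-chain charge at pH 7, and residue
## volume (A^3): physico-chemical descriptors for pair features.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AA_CHARGE <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0.1,
  I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0,
  Y = 0, V = 0
)

AA_VOLUME <- c(
  A = 88.6,  R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G = 60.1,  H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S = 89.0,  T = 116.1, W = 227.8, Y = 193.6, V = 140.0
)

## IUPAC degenerate nucleotide alphabet
IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## Polar substitution suggestions for aggregation-prone aromatics and
## hydrophobics (hotspot redesign).
POLAR_SUBSTITUTIONS <- list(
  Y = c("N", "S"), W = c("S", "N", "F"), F = c("S", "Y"),
  L = c("S", "T"), I = c("T", "S"), V = c("T", "S"), M = c("S", "T"),
  A = c("S"), C = c("S"), P = character(0), G = character(0)
)

## Backbone heavy-atom names (everything else in a residue is side chain;
## CA counts as backbone, glycine has no side-chain heavy atom).
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
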