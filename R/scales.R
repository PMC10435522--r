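# Published per-residue scales used by the antigenicity predictors, the SASA
# machinery and the RSA normalization. Values are keyed by one-letter code.

# Emini surface-accessibility propensities (6-residue window product scale).
EMINI_SCALE <- c(
  A = 0.815, R = 1.475, N = 1.296, D = 1.283, C = 0.394,
  Q = 1.348, E = 1.445, G = 0.714, H = 1.180, I = 0.603,
  L = 0.603, K = 1.545, M = 0.714, F = 0.695, P = 1.236,
  S = 1.115, T = 1.184, W = 0.808, Y = 1.089, V = 0.606
)

# Kolaskar-Tongaonkar antigenic propensities (7-residue moving average).
KOLASKAR_SCALE <- c(
  A = 1.064, R = 0.873, N = 0.776, D = 0.866, C = 1.412,
  Q = 1.015, E = 0.851, G = 0.874, H = 1.105, I = 1.152,
  L = 1.250, K = 0.930, M = 0.826, F = 1.091, P = 1.064,
  S = 1.012, T = 0.909, W = 0.893, Y = 1.161, V = 1.383
)

# Parker hydrophilicity (7-residue moving average); stands in for an
# HMM-based linear-epitope predictor as the third concordant profile.
PARKER_SCALE <- c(
  A = 2.1, R = 4.2, N = 7.0, D = 10.0, C = 1.4,
  Q = 6.0, E = 7.8, G = 5.7, H = 2.1, I = -8.0,
  L = -9.2, K = 5.7, M = -4.2, F = -9.2, P = 2.1,
  S = 6.5, T = 5.2, W = -10.0, Y = -1.9, V = -3.7
)

# Theoretical maximum accessible surface areas (A^2) per residue type,
# Gly-X-Gly based; denominator of relative solvent accessibility.
MAX_ASA_TIEN <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# Element-keyed van der Waals radii (A) for SASA and clash detection.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, H = 1.20)

#' Van der Waals radii for a vector of element symbols
#'
#' Unknown elements receive `default` (with a warning), so structures with
#' exotic ligand chemistry still get a finite, documented radius.
#'
#' @param element character vector of element symbols.
#' @param default radius in Angstrom used for elements not in the table.
#' @return numeric vector of radii, same length as `element`.
#' @export
vdw_radius <- function(element, default = 1.8) {
  r <- VDW_RADII[toupper(element)]
  if (anyNA(r)) {
    warn(paste0("unknown element(s) ", paste(unique(element[is.na(r)]), collapse = ", "),
                "; using default radius ", default, " A"))
    r[is.na(r)] <- default
  }
  unname(r)
}

# Side-chain heavy atoms in canonical (outward) order; used by the
# common-atom truncation model in substitution_impact().
SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB","CG","CD","NE","CZ","NH1","NH2"),
  ASN = c("CB","CG","OD1","ND2"),
  ASP = c("CB","CG","OD1","OD2"),
  CYS = c("CB","SG"),
  GLN = c("CB","CG","CD","OE1","NE2"),
  GLU = c("CB","CG","CD","OE1","OE2"),
  GLY = character(0),
  HIS = c("CB","CG","ND1","CD2","CE1","NE2"),
  ILE = c("CB","CG1","CG2","CD1"),
  LEU = c("CB","CG","CD1","CD2"),
  LYS = c("CB","CG","CD","CE","NZ"),
  MET = c("CB","CG","SD","CE"),
  PHE = c("CB","CG","CD1","CD2","CE1","CE2","CZ"),
  PRO = c("CB","CG","CD"),
  SER = c("CB","OG"),
  THR = c("CB","OG1","CG2"),
  TRP = c("CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"),
  TYR = c("CB","CG","CD1","CD2","CE1","CE2","CZ","OH"),
  VAL = c("CB","CG1","CG2")
)

# Hydrogen-bond donor / acceptor heavy atoms per residue type (backbone N is
# a donor except proline; backbone O always accepts). Hydroxyls both donate
# and accept; His ring nitrogens are treated as both.
HB_DONORS <- list(
  ARG = c("NE","NH1","NH2"), LYS = c("NZ"), ASN = c("ND2"), GLN = c("NE2"),
  HIS = c("ND1","NE2"), TRP = c("NE1"), SER = c("OG"), THR = c("OG1"),
  TYR = c("OH"), CYS = c("SG")
)
HB_ACCEPTORS <- list(
  ASP = c("OD1","OD2"), GLU = c("OE1","OE2"), ASN = c("OD1"), GLN = c("OE1"),
  HIS = c("ND1","NE2"), SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  MET = c("SD")
)
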