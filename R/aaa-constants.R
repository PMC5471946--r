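# Shared amino-acid tables and controlled vocabularies.

#' Standard amino-acid one-letter codes
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residues tolerated in input sequences but excluded from composition
# denominators and from pI / PEST / moment scoring.
NONSTANDARD_AA <- c("X", "B", "Z", "U")

#' Eisenberg normalized consensus hydrophobicity scale
#' @keywords internal
EISENBERG_SCALE <- c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
  Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
  L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
  S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

# Kyte-Doolittle hydropathy, used (rescaled to [0, 90]) inside PEST scoring.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Average residue (monomer minus water) masses in Daltons, for the
# mass-weighted DEPST percentage of the PEST score.
RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)

#' Default pKa table (EMBOSS-style) for the isoelectric-point solver
#'
#' Named list with `nterm`, `cterm` and side-chain pKa values for the
#' ionizable residues K, R, H (basic) and D, E, C, Y (acidic).
#' @export
default_pka_table <- function() {
  list(nterm = 8.6, cterm = 3.6,
       K = 10.8, R = 12.5, H = 6.5,
       D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
}

#' Default amino-acid grouping table (pepstats-style)
#'
#' Nine physicochemical groups used for the group-fraction descriptors.
#' @return named list of character vectors of one-letter codes
#' @export
default_aa_groups <- function() {
  list(
    tiny        = c("A", "C", "G", "S", "T"),
    small       = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
    aliphatic   = c("A", "I", "L", "V"),
    aromatic    = c("F", "H", "W", "Y"),
    hydrophobic = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y"),
    polar       = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
    charged     = c("D", "E", "H", "K", "R"),
    basic       = c("H", "K", "R"),
    acidic      = c("D", "E"))
}

#' The ten-term subcellular location vocabulary
#' @export
location_vocabulary <- function() {
  c("cytoplasm", "cytoskeleton", "endoplasmic reticulum", "extracellular",
    "Golgi apparatus", "lysosome", "mitochondrion", "nucleus",
    "peroxisome", "plasma membrane")
}

#' The three post-translational modification types considered
#' @export
ptm_types <- function() c("phosphorylation", "ubiquitination", "acetylation")
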