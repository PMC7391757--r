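# Residue-level lookup tables used across the annotation and generator code.

# Kyte-Doolittle hydropathy index
.KD <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# average residue masses (Da); peptide mass = sum + 18.02 (one water)
.AA_MASS <- c(
  A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14, E = 129.12,
  Q = 128.13, G = 57.05, H = 137.14, I = 113.16, L = 113.16, K = 128.17,
  M = 131.19, F = 147.18, P = 97.12, S = 87.08, T = 101.10, W = 186.21,
  Y = 163.18, V = 99.13
)
.MASS_WATER <- 18.02
.MASS_X <- 110  # average residue stand-in for unknown residues

# side-chain charge at physiological pH (His counted half-protonated)
.AA_CHARGE <- c(K = 1, R = 1, H = 0.5, D = -1, E = -1)

.HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W", "C")

.AA20 <- names(.AA_MASS)
.PROTEIN_ALPHABET <- c(.AA20, "X", "*")
.NT_ALPHABET <- c("A", "C", "G", "T", "N")

# the seven sequencing libraries of the red king crab tissue panel
.TABLE2_LIBS <- c("B-top", "C-top", "A-belly", "A-legm", "C-legm",
                  "A-legs", "C-legs")

# cleavage-site position sets of the (-3,-1) rule
.SP_MINUS1 <- c("A", "G", "S", "C", "T", "Q")
.SP_MINUS3 <- c("A", "G", "S", "C", "T", "V", "L", "I")

.FAMILY_PREFIX <- c(
  buforin = "PcBuf", acipensin = "PcAcp", ubiquicidin = "PcUbi",
  lysozyme = "PcLys", beta_thymosin = "PcBThm", crustin = "PcCrs",
  paralithocin = "PcPar", kazal = "PcKaz", alf = "PcALF", other = "PcAMP"
)

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.net_charge <- function(chars) {
  sum(.AA_CHARGE[chars], na.rm = TRUE)
}
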