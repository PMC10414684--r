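# Residue-level constants shared across the package.
# Masses are the standard CODATA-derived residue masses used throughout
# proteomics (monoisotopic to 5 decimals, average to 4).

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

.MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

.AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

.MASS_WATER_MONO <- 18.010565
.MASS_WATER_AVG  <- 18.0153
.MASS_PROTON     <- 1.007276

# Post-translational modification deltas (monoisotopic unless noted)
.MOD_DELTA <- c(
  pyro_glu  = -17.026549,
  oxidation = 15.994915,
  sulfation = 79.956815,
  amide     = -0.984016)
.MOD_DELTA_AVG_AMIDE <- -0.9848

# Kyte-Doolittle hydropathy
.KD <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Eisenberg consensus hydrophobicity (for the helical hydrophobic moment)
.EISENBERG <- c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85,
  E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
  M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
  Y = 0.26, V = 1.08)

# Residues counted as hydrophobic for the hydrophobic-% descriptor
.HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")

# round() uses banker's rounding; reported percentages, microM values and
# coverage use conventional half-up rounding instead.
.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

.splitResidues <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

.checkStandardResidues <- function(sequence, what = "sequence") {
  res <- .splitResidues(sequence)
  bad <- which(!res %in% .AA20)
  if (length(bad))
    stop(sprintf("non-standard residue '%s' at position %d in %s",
                 res[bad[1]], bad[1], what), call. = FALSE)
  invisible(res)
}
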