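# Pinned physical constants: one fixed isotope table so that fine-structure
# results (e.g. the M+1 isotopologue shares) are reproducible to the digit.

#' @keywords internal
PROTON_MASS <- 1.007276467

# IUPAC/AME atomic masses (Da) and representative isotopic abundances.
# Each element: data.frame of isotopes ordered by mass number; `shift` is the
# nominal mass shift relative to the most abundant (light) isotope.
ISOTOPE_TABLE <- list(
  C = data.frame(label = c("12C", "13C"),
                 mass = c(12.0, 13.00335483507),
                 abundance = c(0.9893, 0.0107),
                 shift = c(0L, 1L)),
  H = data.frame(label = c("1H", "2H"),
                 mass = c(1.00782503207, 2.01410177785),
                 abundance = c(0.999885, 0.000115),
                 shift = c(0L, 1L)),
  N = data.frame(label = c("14N", "15N"),
                 mass = c(14.00307400443, 15.00010889888),
                 abundance = c(0.99636, 0.00364),
                 shift = c(0L, 1L)),
  O = data.frame(label = c("16O", "17O", "18O"),
                 mass = c(15.99491461957, 16.99913175650, 17.99915961286),
                 abundance = c(0.99757, 0.00038, 0.00205),
                 shift = c(0L, 1L, 2L)),
  S = data.frame(label = c("32S", "33S", "34S", "36S"),
                 mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001),
                 shift = c(0L, 1L, 2L, 4L)),
  P = data.frame(label = "31P",
                 mass = 30.97376199842,
                 abundance = 1.0,
                 shift = 0L)
)

# Monoisotopic (most abundant isotope) mass per element.
MONO_MASS <- vapply(ISOTOPE_TABLE, function(tab) tab$mass[1], numeric(1))

# Residue (in-chain, dehydrated) elemental compositions of the 20 amino acids.
AMINO_ACIDS <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

# Post-translational modification composition deltas.
# acetyl +C2H2O (42.0106 Da); trimethyl +3xCH2 (42.0470 Da);
# biotinyl +C10H14N2O2S (side-chain amide on lysine).
MODIFICATIONS <- list(
  acetyl    = c(C = 2, H = 2, O = 1),
  trimethyl = c(C = 3, H = 6),
  biotinyl  = c(C = 10, H = 14, N = 2, O = 2, S = 1)
)

# Aliases accepted in bracket notation and configs.
MODIFICATION_ALIASES <- c(ac = "acetyl", me3 = "trimethyl", "3m" = "trimethyl",
                          bio = "biotinyl", acetyl = "acetyl",
                          trimethyl = "trimethyl", biotinyl = "biotinyl")
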