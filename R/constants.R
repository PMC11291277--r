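# Physical constants for peptide mass and isotope-envelope calculations.
# Monoisotopic residue masses (Da), standard values; X is disallowed in
# mass computations but tolerated in sequence handling as "unknown".

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565
HYDROXYLATION_SHIFT <- 15.994915  # +O on proline (hydroxyproline)
DEAMIDATION_SHIFT <- 0.984016     # Q->E / N->D, -NH +O
ISOTOPE_SPACING <- 1.00336        # average 13C-driven isotope step, Da

RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

AMINO_ACIDS <- names(RESIDUE_MASS)

# Residue elemental compositions (no water), rows C,H,N,O,S.
RESIDUE_FORMULA <- rbind(
  C = c(G = 2, A = 3, S = 3, P = 5, V = 5, T = 4, C = 3, L = 6, I = 6,
        N = 4, D = 4, Q = 5, K = 6, E = 5, M = 5, H = 6, F = 9, R = 6,
        Y = 9, W = 11),
  H = c(G = 3, A = 5, S = 5, P = 7, V = 9, T = 7, C = 5, L = 11, I = 11,
        N = 6, D = 5, Q = 8, K = 12, E = 7, M = 9, H = 7, F = 9, R = 12,
        Y = 9, W = 10),
  N = c(G = 1, A = 1, S = 1, P = 1, V = 1, T = 1, C = 1, L = 1, I = 1,
        N = 2, D = 1, Q = 2, K = 2, E = 1, M = 1, H = 3, F = 1, R = 4,
        Y = 1, W = 2),
  O = c(G = 1, A = 1, S = 2, P = 1, V = 1, T = 2, C = 1, L = 1, I = 1,
        N = 2, D = 3, Q = 2, K = 1, E = 3, M = 1, H = 1, F = 1, R = 1,
        Y = 2, W = 1),
  S = c(G = 0, A = 0, S = 0, P = 0, V = 0, T = 0, C = 1, L = 0, I = 0,
        N = 0, D = 0, Q = 0, K = 0, E = 0, M = 0, H = 0, F = 0, R = 0,
        Y = 0, W = 0)
)

# Natural isotopic abundances, positions M+0, M+1, ... per element.
ELEMENT_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

# Split a peptide string into residues, validating the alphabet.
# allow_x permits 'X' (unknown) for plumbing that does not need a mass.
split_residues <- function(sequence, allow_x = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  allowed <- c(AMINO_ACIDS, if (allow_x) "X")
  bad <- which(!res %in% allowed)
  if (length(bad)) {
    stop(sprintf("non-amino-acid character '%s' at position %d",
                 res[bad[1]], bad[1]), call. = FALSE)
  }
  res
}
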