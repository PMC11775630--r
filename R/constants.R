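# Pinned physical constants (NIST/IUPAC monoisotopic values).  All mass
# arithmetic in the package goes through these tables; nothing is looked up
# at run time, so results are identical across platforms.

#' @keywords internal
PROTON_MASS <- 1.00727646688

# Monoisotopic atomic masses, Da.  "O18" is treated as a distinct element
# species so that heavy C-terminal labels survive composition arithmetic.
ATOMIC_MASS <- c(
  C   = 12.0,
  H   = 1.00782503207,
  N   = 14.0030740048,
  O   = 15.99491461956,
  S   = 31.97207100,
  P   = 30.97376163,
  O18 = 17.99916040
)

# Natural isotope masses and abundances used for theoretical isotope
# patterns.  One matrix per element, columns: mass (Da), abundance.
ISOTOPE_TABLE <- list(
  C = cbind(mass = c(12.0, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  H = cbind(mass = c(1.00782503207, 2.0141017778),
            abundance = c(0.999885, 0.000115)),
  N = cbind(mass = c(14.0030740048, 15.0001088982),
            abundance = c(0.99636, 0.00364)),
  O = cbind(mass = c(15.99491461956, 16.9991317, 17.999161),
            abundance = c(0.99757, 0.00038, 0.00205)),
  S = cbind(mass = c(31.972071, 32.97145876, 33.9678669, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = cbind(mass = 30.97376163, abundance = 1.0),
  # an installed 18-O label is isotopically pure by construction
  O18 = cbind(mass = 17.99916040, abundance = 1.0)
)

# Elemental compositions of amino-acid residues (peptide-bond residues,
# i.e. the free amino acid minus water).  Rows: residue one-letter code.
RESIDUE_FORMULA <- local({
  m <- rbind(
    G = c(2, 3, 1, 1, 0, 0),
    A = c(3, 5, 1, 1, 0, 0),
    S = c(3, 5, 1, 2, 0, 0),
    P = c(5, 7, 1, 1, 0, 0),
    V = c(5, 9, 1, 1, 0, 0),
    T = c(4, 7, 1, 2, 0, 0),
    C = c(3, 5, 1, 1, 1, 0),
    L = c(6, 11, 1, 1, 0, 0),
    I = c(6, 11, 1, 1, 0, 0),
    N = c(4, 6, 2, 2, 0, 0),
    D = c(4, 5, 1, 3, 0, 0),
    Q = c(5, 8, 2, 2, 0, 0),
    K = c(6, 12, 2, 1, 0, 0),
    E = c(5, 7, 1, 3, 0, 0),
    M = c(5, 9, 1, 1, 1, 0),
    H = c(6, 7, 3, 1, 0, 0),
    F = c(9, 9, 1, 1, 0, 0),
    R = c(6, 12, 4, 1, 0, 0),
    Y = c(9, 9, 1, 2, 0, 0),
    W = c(11, 10, 2, 1, 0, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S", "P")
  m
})

# Monoisotopic residue masses derived once from the formula table.
RESIDUE_MASS <- drop(RESIDUE_FORMULA %*% ATOMIC_MASS[colnames(RESIDUE_FORMULA)])

#' Standard amino-acid one-letter codes known to the package
#' @return Character vector of the 20 residue codes.
#' @export
amino_acids <- function() rownames(RESIDUE_FORMULA)
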