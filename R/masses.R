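# Monoisotopic residue masses (Da), 20 standard amino acids.
# Cysteine is carried as the carbamidomethylated residue (+57.02146 Da,
# iodoacetamide alkylation as fixed modification).
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919 + 57.02146, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259,
  M = 131.04049, H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333,
  W = 186.07931
)

MASS_WATER  <- 18.010565
MASS_PROTON <- 1.00728

AA_ALPHABET <- names(RESIDUE_MASS)

#' Monoisotopic peptide mass
#'
#' Computes the monoisotopic mass of a peptide as the sum of its residue
#' masses plus one water. Cysteines are treated as carbamidomethylated
#' (fixed +57.02146 Da); no variable modifications are considered.
#'
#' @param sequence Character vector of peptide sequences (uppercase,
#'   20-letter amino-acid alphabet).
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' peptide_mass("ACK")
#' peptide_mass(c("G", "PEPTIDE"))
#' @export
peptide_mass <- function(sequence) {
  if (length(sequence) == 0L) return(numeric(0))
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) stop("empty peptide sequence")
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!aa %in% AA_ALPHABET)
    if (length(bad)) {
      stop(sprintf("unknown residue '%s' at position %d in '%s'",
                   aa[bad[1]], bad[1], s))
    }
    sum(RESIDUE_MASS[aa]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

#' Admissible charge states for a peptide mass
#'
#' Returns the charge states for which the ion m/z = (mass + z * 1.00728)/z
#' falls inside the recorded scan window (default m/z 250-1500, matching a
#' wide acquisition range chosen to retain short unique peptides). A peptide
#' is admissible for quantification iff the returned set is non-empty.
#'
#' @param mass Monoisotopic mass in Da (single positive number).
#' @param charges Integer charge states to consider, subset of 1..6.
#' @param window Numeric length-2, inclusive m/z window.
#' @return Integer vector of admissible charges (possibly empty).
#' @examples
#' mz_admissible(377.17328, charges = c(1, 2))
#' @export
mz_admissible <- function(mass, charges = 2:4, window = c(250, 1500)) {
  if (!is.numeric(mass) || length(mass) != 1L || is.na(mass) || mass <= 0)
    stop("mass must be a single positive number")
  charges <- as.integer(charges)
  if (length(charges) && (any(charges < 1L) || any(charges > 6L)))
    stop("charges must lie in 1..6")
  mz <- (mass + charges * MASS_PROTON) / charges
  sort(charges[mz >= window[1] & mz <= window[2]])
}
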