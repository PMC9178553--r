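# Monoisotopic m/z calculators for y ions and precursors.

#' y-ion m/z
#'
#' Monoisotopic mass-to-charge of the y ion of length `ordinal`: the sum of
#' the C-terminal `ordinal` residue masses plus water, protonated `z` times.
#'
#' @param sequence Peptide sequence (canonical residues).
#' @param ordinal Fragment length k (number of C-terminal residues), `1 <= k
#'   <= nchar(sequence) - 1`. Vectorized.
#' @param fragment_charge Fragment charge z (>= 1). Vectorized with `ordinal`.
#' @return Numeric m/z in Thomson.
#' @export
y_ion_mz <- function(sequence, ordinal, fragment_charge = 1L) {
  validate_sequence(sequence)
  res <- split_residues(sequence)
  L <- length(res)
  if (any(ordinal < 1L | ordinal > L - 1L)) {
    stop("`ordinal` must lie in [1, length - 1]", call. = FALSE)
  }
  if (any(fragment_charge < 1L)) stop("`fragment_charge` must be >= 1", call. = FALSE)
  csum <- cumsum(rev(unname(AA_MONO_MASS[res])))  # mass of k C-terminal residues
  (csum[ordinal] + MASS_WATER + fragment_charge * MASS_PROTON) / fragment_charge
}

#' Precursor m/z
#'
#' @param sequence Peptide sequence.
#' @param charge Precursor charge (>= 1).
#' @return Numeric m/z in Thomson.
#' @export
precursor_mz <- function(sequence, charge = 2L) {
  validate_sequence(sequence)
  if (any(charge < 1L)) stop("`charge` must be >= 1", call. = FALSE)
  m <- sum(AA_MONO_MASS[split_residues(sequence)]) + MASS_WATER
  (m + charge * MASS_PROTON) / charge
}
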