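# Shared constants: amino-acid alphabet, monoisotopic masses, tensor geometry.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes in alphabetical order. This
#' ordering defines the column order of the one-hot sequence encoding and the
#' numeric residue codes of the sliding-window matrix.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Monoisotopic residue masses (Da), canonical residues only.
AA_MONO_MASS <- c(
  A = 71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G = 57.021464,  H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P = 97.052764,  Q = 128.058578, R = 156.101111, S = 87.032028,
  T = 101.047679, V = 99.068414,  W = 186.079313, Y = 163.063329
)

MASS_WATER  <- 18.010565
MASS_PROTON <- 1.007276

# Target-tensor geometry: y1..y14 at fragment charge 1..3.
MAX_ORDINAL    <- 14L
MAX_FRAG_Z     <- 3L
N_SLOTS        <- 42L
MIN_PEP_LENGTH <- 6L
MAX_PEP_LENGTH <- 15L

aa_index <- function(residues) {
  idx <- match(residues, aa_alphabet())
  if (anyNA(idx)) {
    bad <- unique(residues[is.na(idx)])
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

split_residues <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  if (grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), sequence)) {
    bad <- setdiff(unique(split_residues(sequence)), aa_alphabet())
    stop("sequence contains non-canonical residue(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}
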