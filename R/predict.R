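# User-facing prediction: peptide list in, annotated 42-slot intensity
# table out.

#' Predict y-ion intensities for peptides
#'
#' Accepts a tibble with columns `sequence` (required), `precursor_charge`
#' and `collision_energy` (filled in with the defaults when absent), a
#' character vector of `SEQUENCE[/charge[/CE]]` lines, or a path to such a
#' list. Peptides outside the supported length range 6-15 (or with
#' non-canonical residues) are rejected; the rejected rows are attached as
#' the `"rejected"` attribute and reported with a warning.
#'
#' @param model A trained `yfrag_model` or `yfrag_fit`.
#' @param peptides Peptide input (see Details).
#' @param clamp Truncate negative predictions to 0 (default `TRUE`); the raw
#'   network output is linear and may dip below zero.
#' @param default_charge,default_ce Fill-ins for missing charge / CE.
#' @return A tibble with one row per peptide and slot: `sequence`,
#'   `precursor_charge`, `collision_energy`, `ion` (label such as `y3` or
#'   `y5^2`), `ordinal`, `fragment_charge`, `slot`, `feasible`, `mz` (`NA`
#'   for infeasible slots) and `intensity`.
#' @export
predict_intensities <- function(model, peptides, clamp = TRUE,
                                default_charge = 2L, default_ce = 30) {
  if (inherits(model, "yfrag_fit")) model <- model$model
  if (is.character(peptides)) {
    peptides <- read_peptide_list(peptides, default_charge, default_ce)
  }
  peptides <- tibble::as_tibble(peptides)
  if (is.null(peptides$precursor_charge)) peptides$precursor_charge <- default_charge
  if (is.null(peptides$collision_energy)) peptides$collision_energy <- default_ce
  peptides$precursor_charge[is.na(peptides$precursor_charge)] <- default_charge
  peptides$collision_energy[is.na(peptides$collision_energy)] <- default_ce

  reason <- vapply(seq_len(nrow(peptides)), function(i) {
    s <- peptides$sequence[i]
    if (grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), s))
      return("non-canonical residue")
    if (nchar(s) < MIN_PEP_LENGTH || nchar(s) > MAX_PEP_LENGTH)
      return(sprintf("length %d outside [6, 15]", nchar(s)))
    if (!peptides$precursor_charge[i] %in% 1:3)
      return("precursor charge outside [1, 3]")
    ""
  }, character(1))
  rejected <- dplyr::mutate(peptides[reason != "", ], reason = reason[reason != ""])
  if (nrow(rejected)) {
    warning(sprintf("%d peptide(s) rejected; see attr(., 'rejected')",
                    nrow(rejected)), call. = FALSE)
  }
  ok <- peptides[reason == "", ]
  if (!nrow(ok)) {
    out <- tibble::tibble(sequence = character(), precursor_charge = integer(),
                          collision_energy = numeric(), ion = character(),
                          ordinal = integer(), fragment_charge = integer(),
                          slot = integer(), feasible = logical(),
                          mz = numeric(), intensity = numeric())
    attr(out, "rejected") <- rejected
    return(out)
  }

  lib <- speclib(sequence = ok$sequence, precursor_charge = ok$precursor_charge,
                 collision_energy = ok$collision_energy,
                 peaks = rep(list(peak_tbl()), nrow(ok)), source = "query")
  ds <- encode_library(lib, with_targets = FALSE)
  pred <- predict_matrix(model, ds)
  if (clamp) pred <- pmax(pred, 0)

  ions <- ion_of(seq_len(N_SLOTS))
  out <- purrr::map_dfr(seq_len(nrow(ok)), function(i) {
    feas <- ds$mask[i, ]
    mz <- rep(NA_real_, N_SLOTS)
    fi <- which(feas)
    mz[fi] <- vapply(fi, function(s)
      y_ion_mz(ok$sequence[i], ions$ordinal[s], ions$fragment_charge[s]),
      numeric(1))
    tibble::tibble(sequence = ok$sequence[i],
                   precursor_charge = ok$precursor_charge[i],
                   collision_energy = ok$collision_energy[i],
                   ion = paste0("y", ions$ordinal,
                                ifelse(ions$fragment_charge > 1L,
                                       paste0("^", ions$fragment_charge), "")),
                   ordinal = ions$ordinal, fragment_charge = ions$fragment_charge,
                   slot = seq_len(N_SLOTS), feasible = feas, mz = mz,
                   intensity = pred[i, ])
  })
  attr(out, "rejected") <- rejected
  out
}
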