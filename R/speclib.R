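# The spectral-library container: a tibble with one row per precursor and a
# `peaks` list-column of per-peak tibbles.

#' Construct a spectral library
#'
#' A `speclib` is a tibble with one row per peptide precursor and columns
#' `sequence`, `precursor_charge`, `collision_energy`, `source`, and `peaks`.
#' Each element of `peaks` is a tibble with columns `series` (ion-series
#' label; only `"y"` after cleaning), `ordinal` (fragment length k),
#' `fragment_charge`, `mz` and `intensity`. The identity key of a spectrum is
#' (`sequence`, `precursor_charge`): the same sequence at a different charge
#' state is a distinct peptide.
#'
#' @param sequence Character vector of peptide sequences.
#' @param precursor_charge Integer vector of precursor charge states.
#' @param collision_energy Numeric vector of collision energies (eV); may be
#'   `NA` when the source library does not record CE.
#' @param peaks List of peak tibbles (see Details).
#' @param source Character vector of free-text provenance tags.
#' @return A tibble of class `speclib`.
#' @export
speclib <- function(sequence = character(), precursor_charge = integer(),
                    collision_energy = NA_real_, peaks = list(),
                    source = NA_character_) {
  out <- tibble::tibble(
    sequence = as.character(sequence),
    precursor_charge = as.integer(precursor_charge),
    collision_energy = as.numeric(collision_energy),
    source = as.character(source),
    peaks = if (length(sequence)) peaks else list()
  )
  new_speclib(out)
}

#' @rdname speclib
#' @param x A data frame with the `speclib` columns.
#' @export
new_speclib <- function(x) {
  needed <- c("sequence", "precursor_charge", "collision_energy", "source", "peaks")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("not a spectral library; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  class(x) <- c("speclib", class(x))
  x
}

peak_tbl <- function(series = character(), ordinal = integer(),
                     fragment_charge = integer(), mz = numeric(),
                     intensity = numeric()) {
  tibble::tibble(
    series = as.character(series),
    ordinal = as.integer(ordinal),
    fragment_charge = as.integer(fragment_charge),
    mz = as.numeric(mz),
    intensity = as.numeric(intensity)
  )
}

n_peaks <- function(lib) vapply(lib$peaks, nrow, integer(1))

#' @export
print.speclib <- function(x, ...) {
  cat(sprintf("# Spectral library: %d spectra, %d peaks\n",
              nrow(x), sum(n_peaks(x))))
  NextMethod()
}

# dplyr verbs drop subclasses; restore after row filtering etc.
as_speclib <- function(x) {
  if (!inherits(x, "speclib")) x <- new_speclib(x)
  x
}

#' Flatten a library to one row per peak
#'
#' @param lib A `speclib`.
#' @return A tibble with one row per annotated peak, carrying the precursor
#'   columns alongside the peak columns and a `peptide_id` row index.
#' @export
peaks_long <- function(lib) {
  lib |>
    dplyr::mutate(peptide_id = dplyr::row_number(),
                  length = nchar(.data$sequence)) |>
    tidyr::unnest("peaks")
}
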