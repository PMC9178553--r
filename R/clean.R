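# Library cleaning pipeline: strip modifications, keep y ions only,
# deduplicate across sources, drop sparse spectra.

#' Remove modification markup from sequences
#'
#' Modified residues (bracketed or parenthesised mass tags, lowercase
#' letters) are collapsed to their unmodified canonical residue; the peptide
#' is then treated as unmodified. Peaks are left untouched.
#'
#' @param lib A [speclib()].
#' @return The library with canonical uppercase sequences.
#' @export
strip_modifications <- function(lib) {
  stripped <- gsub("\\[[^]]*\\]|\\(([^)]*)\\)", "", lib$sequence)
  stripped <- toupper(stripped)
  bad_re <- sprintf("[^%s]", paste(aa_alphabet(), collapse = ""))
  bad <- grepl(bad_re, stripped)
  if (any(bad)) {
    tok <- regmatches(stripped[bad][1], regexpr(bad_re, stripped[bad][1]))
    stop(sprintf("sequence '%s' contains residue '%s' with no canonical mapping",
                 lib$sequence[bad][1], tok), call. = FALSE)
  }
  lib$sequence <- stripped
  lib
}

#' Keep representable y-ion peaks only
#'
#' Removes every peak that is not a y ion, plus y ions the 42-slot target
#' tensor cannot represent: fragment charge above 3, ordinal above 14, or
#' ordinal at or beyond the peptide length.
#'
#' @param lib A [speclib()].
#' @return The library with filtered `peaks`.
#' @export
drop_b_ions <- function(lib) {
  len <- nchar(lib$sequence)
  lib$peaks <- purrr::map2(lib$peaks, len, function(pk, L) {
    keep <- pk$series == "y" & !is.na(pk$ordinal) &
      pk$ordinal >= 1L & pk$ordinal <= min(MAX_ORDINAL, L - 1L) &
      pk$fragment_charge >= 1L & pk$fragment_charge <= MAX_FRAG_Z
    keep[is.na(keep)] <- FALSE
    pk[keep, , drop = FALSE]
  })
  lib
}

#' Merge libraries, keeping one spectrum per peptide
#'
#' Peptides found in more than one source library are reduced to the single
#' spectrum with the highest number of peaks; ties keep the copy from the
#' earliest source. The same sequence at different precursor charges counts
#' as different peptides.
#'
#' @param libs A list of [speclib()] objects (one per source), or a single
#'   `speclib`.
#' @return A deduplicated [speclib()].
#' @export
deduplicate <- function(libs) {
  if (inherits(libs, "speclib")) libs <- list(libs)
  merged <- dplyr::bind_rows(lapply(seq_along(libs), function(i)
    dplyr::mutate(tibble::as_tibble(libs[[i]]), .src_rank = i)))
  if (!nrow(merged)) return(speclib())
  merged$.n_peaks <- vapply(merged$peaks, nrow, integer(1))
  kept <- merged |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(dplyr::desc(.data$.n_peaks), .data$.src_rank, .data$.row) |>
    dplyr::distinct(.data$sequence, .data$precursor_charge, .keep_all = TRUE) |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".src_rank", -".n_peaks", -".row")
  as_speclib(kept)
}

#' Drop spectra with too few peaks
#'
#' @param lib A cleaned [speclib()].
#' @param min_peaks Minimum number of annotated y-ion peaks a spectrum must
#'   have to be retained (default 3).
#' @return The filtered library, order preserved.
#' @export
filter_min_peaks <- function(lib, min_peaks = 3L) {
  if (!is.numeric(min_peaks) || length(min_peaks) != 1L || min_peaks < 1L) {
    stop("`min_peaks` must be a single integer >= 1", call. = FALSE)
  }
  as_speclib(lib[n_peaks(lib) >= min_peaks, , drop = FALSE])
}

#' Full cleaning pipeline
#'
#' Applies, in order: modification stripping, y-ion filtering, cross-source
#' deduplication, and the minimum-peak filter. The pipeline is idempotent.
#'
#' @param libs A list of source [speclib()] objects or a single `speclib`.
#' @param min_peaks Passed to [filter_min_peaks()].
#' @return A cleaned [speclib()].
#' @export
clean_library <- function(libs, min_peaks = 3L) {
  if (inherits(libs, "speclib")) libs <- list(libs)
  libs |>
    purrr::map(strip_modifications) |>
    purrr::map(drop_b_ions) |>
    deduplicate() |>
    filter_min_peaks(min_peaks = min_peaks)
}

#' Summarize a spectral library
#'
#' @param lib A [speclib()].
#' @return A list with `n_peptides`, `mean_peaks`, `median_peaks`, and a
#'   `histogram` tibble (`n_peaks`, `count`) over peaks-per-spectrum. For an
#'   empty library the mean and median are `NA` and `undefined` is `TRUE`.
#' @export
library_summary <- function(lib) {
  np <- n_peaks(lib)
  if (!length(np)) {
    return(list(n_peptides = 0L, mean_peaks = NA_real_, median_peaks = NA_real_,
                undefined = TRUE,
                histogram = tibble::tibble(n_peaks = integer(), count = integer())))
  }
  hist <- tibble::tibble(n_peaks = np) |>
    dplyr::count(.data$n_peaks, name = "count") |>
    dplyr::arrange(.data$n_peaks)
  list(n_peptides = length(np),
       mean_peaks = mean(np),
       median_peaks = stats::median(np),
       undefined = FALSE,
       histogram = hist)
}
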