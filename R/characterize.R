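# Exploratory highest-peak statistics: flanking-residue composition,
# charge-retention profiles, precursor-length co-occurrence, and the gap
# between the two most intense fragments.

#' Highest peak per spectrum
#'
#' For every spectrum, the most intense y ion (ties broken by the smaller
#' slot index) together with its cleavage-site context: residues at
#' positions -2, -1, +1, +2 relative to the cleavage (+1 is the N-terminal
#' residue of the y fragment), whether the fragment retained the precursor
#' charge, and the intensity gap to the second-highest peak.
#'
#' @param lib A cleaned [speclib()]; every spectrum must have at least one
#'   peak.
#' @return A tibble with one row per spectrum: `peptide_id`, `sequence`,
#'   `precursor_charge`, `length`, `ordinal`, `fragment_charge`,
#'   `intensity`, `minus2`, `minus1`, `plus1`, `plus2`, `retained`, `gap`
#'   (`NA` for single-peak spectra).
#' @export
highest_peak <- function(lib) {
  if (any(n_peaks(lib) == 0L)) {
    stop("spectrum without peaks at row ", which(n_peaks(lib) == 0L)[1],
         call. = FALSE)
  }
  long <- peaks_long(lib) |>
    dplyr::mutate(slot = slot_of(.data$ordinal, .data$fragment_charge))
  hp <- long |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::arrange(dplyr::desc(.data$intensity), .data$slot, .by_group = TRUE) |>
    dplyr::summarize(
      sequence = dplyr::first(.data$sequence),
      precursor_charge = dplyr::first(.data$precursor_charge),
      length = dplyr::first(.data$length),
      ordinal = dplyr::first(.data$ordinal),
      fragment_charge = dplyr::first(.data$fragment_charge),
      gap = if (dplyr::n() >= 2L)
        dplyr::first(.data$intensity) - dplyr::nth(.data$intensity, 2L)
      else NA_real_,
      intensity = dplyr::first(.data$intensity),
      .groups = "drop")
  site <- function(offset) {
    pos <- hp$length - hp$ordinal + offset
    ifelse(pos >= 1L & pos <= hp$length, substr(hp$sequence, pos, pos), NA_character_)
  }
  hp |>
    dplyr::mutate(minus2 = site(-1L), minus1 = site(0L),
                  plus1 = site(1L), plus2 = site(2L),
                  retained = .data$fragment_charge == .data$precursor_charge) |>
    dplyr::arrange(.data$peptide_id)
}

#' Flanking-residue count matrix
#'
#' Joint counts of the residues flanking the cleavage of each spectrum's
#' highest peak: rows index the +1 residue (N-terminal residue of the y
#' fragment), columns the -1 residue. Highest peaks at the terminal
#' cleavage (fragment length = precursor length - 1, which has no -2
#' residue) are excluded, as in all window tables here.
#'
#' @param lib A cleaned [speclib()].
#' @param normalize `"none"` (counts, default), `"row"` or `"column"`
#'   frequencies.
#' @return A 20 x 20 matrix over [aa_alphabet()].
#' @export
flanking_matrix <- function(lib, normalize = c("none", "row", "column")) {
  normalize <- match.arg(normalize)
  hp <- highest_peak(lib)
  hp <- hp[hp$ordinal <= hp$length - 2L, , drop = FALSE]
  m <- matrix(0L, 20L, 20L, dimnames = list(plus1 = aa_alphabet(),
                                            minus1 = aa_alphabet()))
  if (nrow(hp)) {
    tab <- table(factor(hp$plus1, aa_alphabet()), factor(hp$minus1, aa_alphabet()))
    m[] <- as.integer(tab)
  }
  switch(normalize,
         none = m,
         row = sweep(m, 1L, pmax(rowSums(m), 1L), "/"),
         column = sweep(m, 2L, pmax(colSums(m), 1L), "/"))
}

#' Residue profile around charge-retaining cleavages
#'
#' Restricted to highest peaks whose fragment retained the precursor charge
#' state, tabulates the amino-acid probability at each position of a window
#' around the cleavage (positions -4..-1 and +1..+4; position +1 is the
#' fragment's N-terminal residue).
#'
#' @param lib A cleaned [speclib()].
#' @param window Positions around the cleavage (default `-4:4`, position 0
#'   is skipped).
#' @return A tibble (`position`, `residue`, `count`, `prob`); per-position
#'   probabilities sum to 1. Empty (with a warning) when no ion retains its
#'   charge.
#' @export
charge_retention_profile <- function(lib, window = -4:4) {
  hp <- highest_peak(lib)
  hp <- hp[hp$retained, , drop = FALSE]
  window <- setdiff(window, 0L)
  if (!nrow(hp)) {
    warning("no charge-retaining highest peaks in library", call. = FALSE)
    return(tibble::tibble(position = integer(), residue = character(),
                          count = integer(), prob = numeric()))
  }
  purrr::map_dfr(window, function(off) {
    pos <- hp$length - hp$ordinal + ifelse(off > 0L, off, off + 1L)
    res <- substr(hp$sequence, pos, pos)
    res <- res[pos >= 1L & pos <= hp$length]
    cnt <- table(factor(res, aa_alphabet()))
    tibble::tibble(position = off, residue = aa_alphabet(),
                   count = as.integer(cnt),
                   prob = as.numeric(cnt) / max(sum(cnt), 1L))
  })
}

#' Precursor-length vs highest-fragment-length counts
#'
#' @param lib A cleaned [speclib()].
#' @return An integer matrix with rows for precursor lengths 6-15 and
#'   columns for highest-fragment lengths 1-14; row sums equal the number
#'   of spectra of each precursor length.
#' @export
length_cooccurrence <- function(lib) {
  hp <- highest_peak(lib)
  tab <- table(factor(hp$length, MIN_PEP_LENGTH:MAX_PEP_LENGTH),
               factor(hp$ordinal, 1:MAX_ORDINAL))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(precursor_length = rownames(tab),
                              fragment_length = colnames(tab)))
  m
}

#' +1-site residue abundance: length-2 fragments vs the rest
#'
#' Counts the +1-site residues of highest peaks split into two strata —
#' fragments of length exactly precursor length - 2, and all others — and
#' correlates the two count profiles across the 20 residues. Each residue's
#' stratum proportions are compared by a two-proportion z statistic;
#' residues whose z score is a robust outlier among the twenty (modified
#' z score above `outlier_z`, the Iglewicz-Hoaglin rule) are reported.
#' Proline is the expected outlier when cleavage enhancement is
#' proline-driven and length-independent.
#'
#' @param lib A cleaned [speclib()].
#' @param outlier_z Modified-z-score threshold (default 3.5).
#' @return A list: `counts` tibble (`residue`, `count_len2`,
#'   `count_other`, `z`), `correlation`, `outliers` (character vector),
#'   `degenerate` flag.
#' @export
plus1_abundance_correlation <- function(lib, outlier_z = 3.5) {
  hp <- highest_peak(lib)
  is_len2 <- hp$ordinal == hp$length - 2L
  c2 <- table(factor(hp$plus1[is_len2], aa_alphabet()))
  co <- table(factor(hp$plus1[!is_len2], aa_alphabet()))
  counts <- tibble::tibble(residue = aa_alphabet(),
                           count_len2 = as.integer(c2),
                           count_other = as.integer(co))
  degenerate <- sum(counts$count_len2) == 0L || sum(counts$count_other) == 0L
  r <- if (degenerate) NA_real_ else pcc(counts$count_len2, counts$count_other)
  outliers <- character(0)
  counts$z <- NA_real_
  if (!degenerate) {
    n1 <- sum(counts$count_len2); n2 <- sum(counts$count_other)
    p1 <- counts$count_len2 / n1; p2 <- counts$count_other / n2
    pp <- (counts$count_len2 + counts$count_other) / (n1 + n2)
    counts$z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    mz <- 0.6745 * (counts$z - stats::median(counts$z)) /
      stats::mad(counts$z, constant = 1)
    outliers <- counts$residue[abs(mz) > outlier_z]
  }
  list(counts = counts, correlation = r, outliers = outliers,
       degenerate = degenerate)
}

#' Intensity gap stratified by proline at +1
#'
#' The difference between the highest and second-highest fragment intensity
#' of each spectrum (spectra with at least two peaks), split by whether the
#' highest peak has proline at its +1 site.
#'
#' @param lib A cleaned [speclib()].
#' @return A list: `data` tibble (`gap`, `proline_plus1`), and
#'   `median_proline` / `median_other`.
#' @export
gap_by_plus1 <- function(lib) {
  hp <- highest_peak(lib)
  hp <- hp[!is.na(hp$gap), , drop = FALSE]
  data <- tibble::tibble(gap = hp$gap, proline_plus1 = hp$plus1 == "P")
  list(data = data,
       median_proline = stats::median(data$gap[data$proline_plus1]),
       median_other = stats::median(data$gap[!data$proline_plus1]))
}
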