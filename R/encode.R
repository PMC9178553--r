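# Feature and target encoding: one-hot sequence, scalar features, sliding
# 4-mer windows, and the 42-slot y-ion intensity tensor.
#
# Slot layout (ordinal-major, charge-minor): slot(k, z) = (k - 1) * 3 + z for
# k in 1..14, z in 1..3 — a bijection onto 1..42. Infeasible slots (k >=
# peptide length, or z above the precursor charge) carry -1 in the target;
# feasible slots without an observed peak carry 0.

#' Slot index of a y ion
#'
#' @param ordinal Fragment length k (1-14).
#' @param fragment_charge Fragment charge z (1-3).
#' @return Integer slot in 1..42. Vectorized.
#' @export
slot_of <- function(ordinal, fragment_charge) {
  stopifnot(all(ordinal >= 1L & ordinal <= MAX_ORDINAL),
            all(fragment_charge >= 1L & fragment_charge <= MAX_FRAG_Z))
  (as.integer(ordinal) - 1L) * 3L + as.integer(fragment_charge)
}

#' Ion identity of a slot
#'
#' Inverse of [slot_of()].
#'
#' @param slot Integer slot in 1..42. Vectorized.
#' @return A tibble with columns `ordinal` and `fragment_charge`.
#' @export
ion_of <- function(slot) {
  stopifnot(all(slot >= 1L & slot <= N_SLOTS))
  slot <- as.integer(slot)
  tibble::tibble(ordinal = (slot - 1L) %/% 3L + 1L,
                 fragment_charge = (slot - 1L) %% 3L + 1L)
}

#' One-hot encode a peptide sequence
#'
#' @param sequence Peptide of length 6 to `max_length`, canonical residues.
#' @param max_length Number of rows of the output (default 15); rows beyond
#'   the sequence length are zero padding.
#' @return A `max_length x 20` 0/1 matrix; columns follow [aa_alphabet()].
#' @export
one_hot_sequence <- function(sequence, max_length = MAX_PEP_LENGTH) {
  validate_sequence(sequence)
  L <- nchar(sequence)
  if (L < MIN_PEP_LENGTH || L > max_length) {
    stop(sprintf("peptide length %d outside supported range [%d, %d]",
                 L, MIN_PEP_LENGTH, max_length), call. = FALSE)
  }
  m <- matrix(0, nrow = max_length, ncol = 20L,
              dimnames = list(NULL, aa_alphabet()))
  m[cbind(seq_len(L), aa_index(split_residues(sequence)))] <- 1
  m
}

#' Scalar feature vector
#'
#' Collision energy, precursor charge, peptide length and proline count —
#' the four scalar inputs of the model. With `standardize = TRUE` (the
#' default used for training) they are scaled to comparable ranges:
#' CE/100, charge/3, length/15, prolines/15.
#'
#' @param sequence Peptide sequence.
#' @param precursor_charge Precursor charge state.
#' @param collision_energy Collision energy in eV; `NA` is treated as the
#'   `default_ce`.
#' @param standardize Scale the features (default `TRUE`).
#' @param default_ce CE used when `collision_energy` is missing.
#' @return Named numeric vector `(ce, charge, length, prolines)`.
#' @export
scalar_features <- function(sequence, precursor_charge, collision_energy = NA,
                            standardize = TRUE, default_ce = 30) {
  validate_sequence(sequence)
  ce <- if (is.na(collision_energy)) default_ce else collision_energy
  len <- nchar(sequence)
  pro <- stringr::str_count(sequence, stringr::fixed("P"))
  out <- c(ce = ce, charge = as.numeric(precursor_charge),
           length = as.numeric(len), prolines = as.numeric(pro))
  if (standardize) {
    out <- out / c(100, MAX_FRAG_Z, MAX_PEP_LENGTH, MAX_PEP_LENGTH)
  }
  out
}

#' Sliding 4-mer window matrix
#'
#' Every 4-mer of the sequence becomes one column of a `window x
#' max_windows` matrix: column j holds residues j..j+window-1 as numeric
#' codes (alphabetical rank scaled by 1/20); a length-15 peptide fills all 12
#' columns, shorter peptides leave zero-padded columns on the right. With
#' `onehot = TRUE` each column is instead the stacked one-hot encoding of its
#' 4-mer (`20 * window` rows).
#'
#' @param sequence Peptide sequence, length >= `window`.
#' @param window 4-mer width (default 4).
#' @param max_windows Number of columns (default 12).
#' @param onehot Use stacked one-hot 4-mer columns instead of rank codes.
#' @return Numeric matrix (`window x max_windows`, or `20*window x
#'   max_windows` when `onehot`).
#' @export
sliding_windows <- function(sequence, window = 4L, max_windows = 12L,
                            onehot = FALSE) {
  validate_sequence(sequence)
  L <- nchar(sequence)
  if (L < window) {
    stop(sprintf("sequence length %d shorter than window %d", L, window),
         call. = FALSE)
  }
  idx <- aa_index(split_residues(sequence))
  nwin <- min(L - window + 1L, max_windows)
  if (onehot) {
    m <- matrix(0, nrow = 20L * window, ncol = max_windows)
    for (j in seq_len(nwin)) {
      res <- idx[j:(j + window - 1L)]
      m[cbind((seq_len(window) - 1L) * 20L + res, j)] <- 1
    }
  } else {
    m <- matrix(0, nrow = window, ncol = max_windows)
    for (j in seq_len(nwin)) m[, j] <- idx[j:(j + window - 1L)] / 20
  }
  m
}

#' Feasible target slots of a precursor
#'
#' A slot (k, z) is feasible iff the fragment fits inside the peptide
#' (`k <= length - 1`) and its charge does not exceed the precursor charge
#' (`z <= precursor_charge`).
#'
#' @param length Peptide length, 6-15.
#' @param precursor_charge Precursor charge, 1-3.
#' @return Logical vector of length 42, `TRUE` where feasible.
#' @export
feasibility_mask <- function(length, precursor_charge) {
  if (length < MIN_PEP_LENGTH || length > MAX_PEP_LENGTH) {
    stop("`length` must lie in [6, 15]", call. = FALSE)
  }
  if (precursor_charge < 1L || precursor_charge > MAX_FRAG_Z) {
    stop("`precursor_charge` must lie in [1, 3]", call. = FALSE)
  }
  ions <- ion_of(seq_len(N_SLOTS))
  ions$ordinal <= length - 1L & ions$fragment_charge <= precursor_charge
}

#' Encode a spectrum's peaks into the 42-slot target
#'
#' Peak intensities are base-peak normalized (maximum intensity becomes 1)
#' and placed at their [slot_of()] positions; feasible slots without a peak
#' are 0 and infeasible slots are -1.
#'
#' @param spectrum A one-row [speclib()] (or a list with `sequence`,
#'   `precursor_charge`, `peaks`).
#' @return A list with `target` (numeric length 42) and `mask` (logical
#'   length 42, `TRUE` = feasible).
#' @export
encode_targets <- function(spectrum) {
  pk <- if (is.data.frame(spectrum$peaks[[1]])) spectrum$peaks[[1]] else spectrum$peaks
  L <- nchar(spectrum$sequence[[1]])
  z_prec <- spectrum$precursor_charge[[1]]
  mask <- feasibility_mask(L, z_prec)
  target <- ifelse(mask, 0, -1)
  if (nrow(pk)) {
    slots <- slot_of(pk$ordinal, pk$fragment_charge)
    infeasible <- !mask[slots]
    if (any(infeasible)) {
      i <- which(infeasible)[1]
      stop(sprintf("peak y%d^%d is infeasible for %s/%d",
                   pk$ordinal[i], pk$fragment_charge[i],
                   spectrum$sequence[[1]], z_prec), call. = FALSE)
    }
    target[slots] <- pk$intensity / max(pk$intensity)
  }
  list(target = target, mask = mask)
}

#' Decode a 42-slot vector back into annotated peaks
#'
#' @param target Numeric vector of length 42.
#' @param length Peptide length.
#' @param precursor_charge Precursor charge.
#' @return A tibble (`ordinal`, `fragment_charge`, `intensity`) of feasible
#'   slots with intensity > 0, sorted by descending intensity; ties keep
#'   slot order.
#' @export
decode_targets <- function(target, length, precursor_charge) {
  if (length(target) != N_SLOTS) {
    stop("`target` must have length 42", call. = FALSE)
  }
  mask <- feasibility_mask(length, precursor_charge)
  keep <- which(mask & target > 0)
  out <- ion_of(keep)
  out$intensity <- target[keep]
  out[order(-out$intensity, keep), , drop = FALSE]
}

#' Encode a cleaned library into model-ready arrays
#'
#' @param lib A cleaned [speclib()] (y ions only, peptide lengths 6-15).
#' @param standardize Passed to [scalar_features()].
#' @param max_length Maximum peptide length / one-hot rows.
#' @param with_targets Encode the 42-slot targets (requires peaks); set
#'   `FALSE` for prediction-only input.
#' @return A `yfrag_dataset`: list with arrays `onehot` (N x 15 x 20),
#'   `features` (N x 4), `windows` (N x 4 x 12), `target` (N x 42), `mask`
#'   (N x 42), and a `meta` tibble.
#' @export
encode_library <- function(lib, standardize = TRUE, max_length = MAX_PEP_LENGTH,
                           with_targets = TRUE) {
  n <- nrow(lib)
  onehot <- array(0, dim = c(n, max_length, 20L))
  feats <- matrix(0, n, 4L, dimnames = list(NULL, c("ce", "charge", "length", "prolines")))
  windows <- array(0, dim = c(n, 4L, 12L))
  target <- matrix(NA_real_, n, N_SLOTS)
  mask <- matrix(NA, n, N_SLOTS)
  for (i in seq_len(n)) {
    onehot[i, , ] <- one_hot_sequence(lib$sequence[i], max_length)
    feats[i, ] <- scalar_features(lib$sequence[i], lib$precursor_charge[i],
                                  lib$collision_energy[i], standardize = standardize)
    windows[i, , ] <- sliding_windows(lib$sequence[i])
    if (with_targets) {
      enc <- encode_targets(lib[i, ])
      target[i, ] <- enc$target
      mask[i, ] <- enc$mask
    } else {
      mask[i, ] <- feasibility_mask(nchar(lib$sequence[i]), lib$precursor_charge[i])
    }
  }
  structure(list(
    onehot = onehot, features = feats, windows = windows,
    target = if (with_targets) target else NULL, mask = mask,
    meta = tibble::tibble(sequence = lib$sequence,
                          precursor_charge = lib$precursor_charge,
                          collision_energy = lib$collision_energy,
                          length = nchar(lib$sequence))
  ), class = "yfrag_dataset")
}

#' @export
print.yfrag_dataset <- function(x, ...) {
  cat(sprintf("# Encoded dataset: %d peptides, %d target slots%s\n",
              nrow(x$meta), N_SLOTS,
              if (is.null(x$target)) " (no targets)" else ""))
  invisible(x)
}

#' Subset an encoded dataset by row
#'
#' @param ds A `yfrag_dataset`.
#' @param idx Integer row indices.
#' @return A `yfrag_dataset` restricted to `idx`.
#' @export
dataset_subset <- function(ds, idx) {
  structure(list(
    onehot = ds$onehot[idx, , , drop = FALSE],
    features = ds$features[idx, , drop = FALSE],
    windows = ds$windows[idx, , , drop = FALSE],
    target = if (!is.null(ds$target)) ds$target[idx, , drop = FALSE],
    mask = ds$mask[idx, , drop = FALSE],
    meta = ds$meta[idx, , drop = FALSE]
  ), class = "yfrag_dataset")
}

#' Number of peptides in an encoded dataset
#'
#' @param ds A `yfrag_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(ds) nrow(ds$meta)

#' Persist an encoded library as a columnar text table
#'
#' One row per peptide: sequence, charge, CE, the 42 target values and the
#' 42 feasibility bits. Numeric values are written with full (17 significant
#' digit) precision so the round trip through [read_encoded()] is bit-exact.
#'
#' @param lib A cleaned [speclib()].
#' @param path Output CSV path.
#' @return Invisibly, the written tibble.
#' @export
write_encoded <- function(lib, path) {
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    enc <- encode_targets(lib[i, ])
    c(list(sequence = lib$sequence[i],
           precursor_charge = lib$precursor_charge[i],
           collision_energy = sprintf("%.17g", lib$collision_energy[i])),
      stats::setNames(as.list(sprintf("%.17g", enc$target)),
                      sprintf("t%02d", seq_len(N_SLOTS))),
      stats::setNames(as.list(as.integer(enc$mask)),
                      sprintf("m%02d", seq_len(N_SLOTS))))
  })
  tbl <- dplyr::bind_rows(rows)
  readr::write_csv(tbl, path)
  invisible(tbl)
}

#' Read a table written by [write_encoded()]
#'
#' @param path CSV path.
#' @return A tibble with `sequence`, `precursor_charge`, `collision_energy`,
#'   a `target` matrix-column and a logical `mask` matrix-column.
#' @export
read_encoded <- function(path) {
  # read numerics as text and convert with strtod, which is correctly
  # rounded, so full-precision values round-trip bit-exactly
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  tcols <- sprintf("t%02d", seq_len(N_SLOTS))
  mcols <- sprintf("m%02d", seq_len(N_SLOTS))
  target <- vapply(tbl[tcols], as.numeric, numeric(nrow(tbl)))
  tibble::tibble(
    sequence = tbl$sequence,
    precursor_charge = as.integer(tbl$precursor_charge),
    collision_energy = as.numeric(tbl$collision_energy),
    target = matrix(target, ncol = N_SLOTS,
                    dimnames = list(NULL, tcols)),
    mask = matrix(as.integer(as.matrix(tbl[mcols])) == 1L, ncol = N_SLOTS)
  )
}
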