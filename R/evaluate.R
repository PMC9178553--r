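# Evaluation statistics: Pearson correlations in the with-zero and
# without-zero senses, high-intensity-peak accuracies, and the full report.

#' Pearson correlation coefficient
#'
#' Standard Pearson correlation. Degenerate inputs (either vector constant)
#' have no defined correlation and return `NA`, which the median summaries
#' exclude.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A number in `[-1, 1]`, or `NA` when undefined.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

resolve_target <- function(spectrum, target, mask) {
  if (!is.null(spectrum)) {
    enc <- encode_targets(spectrum)
    list(target = enc$target, mask = enc$mask)
  } else {
    list(target = target, mask = mask)
  }
}

#' Without-zero Pearson correlation
#'
#' Correlation between prediction and database intensities restricted to
#' the slots where the database spectrum actually has a peak.
#'
#' @param prediction Numeric vector of length 42, aligned to [slot_of()].
#' @param spectrum A one-row [speclib()]; alternatively pass `target` and
#'   `mask` from [encode_targets()] directly.
#' @param target,mask Optional pre-encoded target and feasibility mask.
#' @return PCC, or `NA` when fewer than two database peaks exist.
#' @export
pcc_without_zero <- function(prediction, spectrum = NULL, target = NULL,
                             mask = NULL) {
  enc <- resolve_target(spectrum, target, mask)
  slots <- which(enc$mask & enc$target > 0)
  if (length(slots) < 2L) return(NA_real_)
  pcc(prediction[slots], enc$target[slots])
}

#' With-zero Pearson correlation
#'
#' Correlation over every feasible slot, with zero filled in for fragments
#' the database did not detect.
#'
#' @inheritParams pcc_without_zero
#' @return PCC, or `NA` when undefined.
#' @export
pcc_with_zero <- function(prediction, spectrum = NULL, target = NULL,
                          mask = NULL) {
  enc <- resolve_target(spectrum, target, mask)
  slots <- which(enc$mask)
  if (length(slots) < 2L) return(NA_real_)
  pcc(prediction[slots], enc$target[slots])
}

#' Per-peptide correlation table
#'
#' @param pred `N x 42` prediction matrix.
#' @param ds Encoded dataset with targets (see [encode_library()]).
#' @return A tibble with `sequence`, `precursor_charge`,
#'   `pcc_without_zero`, `pcc_with_zero`.
#' @export
pcc_per_peptide <- function(pred, ds) {
  n <- n_samples(ds)
  wo <- numeric(n); wz <- numeric(n)
  for (i in seq_len(n)) {
    wo[i] <- pcc_without_zero(pred[i, ], target = ds$target[i, ], mask = ds$mask[i, ])
    wz[i] <- pcc_with_zero(pred[i, ], target = ds$target[i, ], mask = ds$mask[i, ])
  }
  tibble::tibble(sequence = ds$meta$sequence,
                 precursor_charge = ds$meta$precursor_charge,
                 pcc_without_zero = wo, pcc_with_zero = wz)
}

db_top_slots <- function(target, mask, k = 3L) {
  present <- which(mask & target > 0)
  present[order(-target[present], present)][seq_len(min(k, length(present)))]
}

#' High-intensity-peak accuracies
#'
#' Three fractions over peptides, mirroring targeted-transition selection:
#' `accuracy_highest` — the predicted most-intense slot equals the database
#' most-intense slot; `accuracy_top1of3` — the predicted most-intense slot
#' is among the database's top three; `accuracy_top2of3` — the two
#' most-intense predicted slots are both among the database's top three.
#' Ties in the database ranking are broken by slot order.
#'
#' @param pred `N x 42` prediction matrix.
#' @param ds Encoded dataset with targets.
#' @return A one-row tibble with the three fractions.
#' @export
highest_peak_accuracy <- function(pred, ds) {
  n <- n_samples(ds)
  if (n == 0L) stop("empty evaluation set", call. = FALSE)
  hits <- matrix(FALSE, n, 3L)
  for (i in seq_len(n)) {
    feas <- which(ds$mask[i, ])
    p <- pred[i, feas]
    pred_rank <- feas[order(-p, feas)]
    db3 <- db_top_slots(ds$target[i, ], ds$mask[i, ], 3L)
    hits[i, 1] <- pred_rank[1] == db3[1]
    hits[i, 2] <- pred_rank[1] %in% db3
    hits[i, 3] <- all(pred_rank[seq_len(min(2L, length(pred_rank)))] %in% db3)
  }
  tibble::tibble(accuracy_highest = mean(hits[, 1]),
                 accuracy_top1of3 = mean(hits[, 2]),
                 accuracy_top2of3 = mean(hits[, 3]))
}

#' Full model evaluation report
#'
#' Computes the per-peptide with-zero and without-zero correlations, their
#' medians, the high-intensity-peak accuracies, and (optionally) the grouped
#' peptide-spectrum-match test.
#'
#' @param model A trained `yfrag_model` (or a `yfrag_fit`).
#' @param lib A cleaned [speclib()] evaluation library.
#' @param psm Run the PSM grouping/match test (default `TRUE`).
#' @param precursor_tol,fragment_tol,min_shared PSM grouping tolerances.
#' @return A `yfrag_eval` report.
#' @export
evaluate_model <- function(model, lib, psm = TRUE, precursor_tol = 0.5,
                           fragment_tol = 0.5, min_shared = 3L) {
  if (inherits(model, "yfrag_fit")) model <- model$model
  ds <- encode_library(lib)
  pred <- predict_matrix(model, ds)
  per_peptide <- pcc_per_peptide(pred, ds)
  acc <- highest_peak_accuracy(pred, ds)
  out <- list(
    per_peptide = per_peptide,
    median_pcc_without_zero = stats::median(per_peptide$pcc_without_zero, na.rm = TRUE),
    median_pcc_with_zero = stats::median(per_peptide$pcc_with_zero, na.rm = TRUE),
    accuracy_highest = acc$accuracy_highest,
    accuracy_top1of3 = acc$accuracy_top1of3,
    accuracy_top2of3 = acc$accuracy_top2of3,
    psm_groups = NA_integer_, psm_mean_group_size = NA_real_,
    psm_match_accuracy = NA_real_
  )
  if (psm) {
    groups <- psm_grouping(lib, precursor_tol, fragment_tol, min_shared)
    out$psm_groups <- if (nrow(groups)) length(unique(groups$group_id)) else 0L
    out$psm_mean_group_size <- if (nrow(groups))
      nrow(groups) / length(unique(groups$group_id)) else NA_real_
    out$psm_match_accuracy <- if (nrow(groups))
      psm_match_accuracy(pred, groups, ds) else NA_real_
  }
  structure(out, class = "yfrag_eval")
}

#' @export
print.yfrag_eval <- function(x, ...) {
  cat(sprintf(paste0(
    "# Evaluation report (%d peptides)\n",
    "  median PCC  without-zero %.4f   with-zero %.4f\n",
    "  highest-peak accuracy %.3f   top1-of-3 %.3f   top2-of-3 %.3f\n"),
    nrow(x$per_peptide), x$median_pcc_without_zero, x$median_pcc_with_zero,
    x$accuracy_highest, x$accuracy_top1of3, x$accuracy_top2of3))
  if (!is.na(x$psm_groups)) {
    cat(sprintf("  PSM groups %d (mean size %.3f), match accuracy %.3f\n",
                x$psm_groups, x$psm_mean_group_size, x$psm_match_accuracy))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param report A `yfrag_eval`.
#' @param json_path Path for the scalar summary (JSON).
#' @param pcc_path Optional path for the per-peptide PCC table (TSV).
#' @return Invisibly, the report.
#' @export
write_eval_report <- function(report, json_path, pcc_path = NULL) {
  scalars <- report[setdiff(names(report), "per_peptide")]
  jsonlite::write_json(scalars, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(pcc_path)) readr::write_tsv(report$per_peptide, pcc_path)
  invisible(report)
}
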