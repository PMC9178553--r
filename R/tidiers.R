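# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained model fit
#'
#' @param x A `yfrag_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`,
#'   `valid_loss`, `lr`).
#' @export
tidy.yfrag_fit <- function(x, ...) x$history

#' @rdname tidy.yfrag_fit
#' @return For `glance`, a one-row tibble (`epochs`, `best_epoch`,
#'   `best_valid_loss`, `n_train`).
#' @export
glance.yfrag_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_valid_loss = x$best_valid_loss, n_train = x$n_train)
}

#' Tidy a cross-validation result
#'
#' @param x A `yfrag_cv`.
#' @param ... Unused.
#' @return The per-fold median-PCC tibble.
#' @export
tidy.yfrag_cv <- function(x, ...) x$fold_pcc

#' @rdname tidy.yfrag_cv
#' @export
glance.yfrag_cv <- function(x, ...) {
  tibble::tibble(folds = nrow(x$fold_pcc),
                 mean_median_pcc = x$mean_median_pcc,
                 sd_median_pcc = x$sd_median_pcc,
                 best_fold = x$best_fold)
}

#' Tidy an evaluation report
#'
#' @param x A `yfrag_eval`.
#' @param ... Unused.
#' @return The per-peptide correlation tibble.
#' @export
tidy.yfrag_eval <- function(x, ...) x$per_peptide

#' @rdname tidy.yfrag_eval
#' @export
glance.yfrag_eval <- function(x, ...) {
  tibble::tibble(
    n_peptides = nrow(x$per_peptide),
    median_pcc_without_zero = x$median_pcc_without_zero,
    median_pcc_with_zero = x$median_pcc_with_zero,
    accuracy_highest = x$accuracy_highest,
    accuracy_top1of3 = x$accuracy_top1of3,
    accuracy_top2of3 = x$accuracy_top2of3,
    psm_groups = x$psm_groups,
    psm_mean_group_size = x$psm_mean_group_size,
    psm_match_accuracy = x$psm_match_accuracy
  )
}
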