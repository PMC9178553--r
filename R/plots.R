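# ggplot2 visualisations of fits, reports and characterization tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot training and validation loss curves
#'
#' @param object A `yfrag_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.yfrag_fit <- function(object, ...) {
  object$history |>
    tidyr::pivot_longer(c("train_loss", "valid_loss"),
                        names_to = "set", values_to = "loss") |>
    dplyr::mutate(set = sub("_loss", "", .data$set)) |>
    ggplot2::ggplot(ggplot2::aes(.data$epoch, .data$loss, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "Loss per epoch") +
    ggplot2::theme_minimal()
}

#' Plot the per-peptide correlation distributions
#'
#' @param object A `yfrag_eval`.
#' @param ... Unused.
#' @return A ggplot (violin per correlation method; undefined values
#'   removed).
#' @export
autoplot.yfrag_eval <- function(object, ...) {
  object$per_peptide |>
    tidyr::pivot_longer(c("pcc_without_zero", "pcc_with_zero"),
                        names_to = "method", values_to = "pcc") |>
    dplyr::filter(!is.na(.data$pcc)) |>
    dplyr::mutate(method = sub("pcc_", "", .data$method)) |>
    ggplot2::ggplot(ggplot2::aes(.data$method, .data$pcc)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.1, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "Pearson correlation",
                  title = "Per-peptide spectral correlation") +
    ggplot2::theme_minimal()
}

matrix_tile_plot <- function(m, xlab, ylab, title) {
  df <- as.data.frame(as.table(m))
  names(df) <- c("row", "col", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = xlab, y = ylab, title = title, fill = "count") +
    ggplot2::theme_minimal()
}

#' Heatmap of the flanking-residue count matrix
#'
#' @param lib A cleaned [speclib()] (or a matrix from [flanking_matrix()]).
#' @param ... Passed to [flanking_matrix()].
#' @return A ggplot.
#' @export
plot_flanking_matrix <- function(lib, ...) {
  m <- if (is.matrix(lib)) lib else flanking_matrix(lib, ...)
  matrix_tile_plot(m, "fragment site -1", "fragment site +1",
                   "Residues flanking the highest-peak cleavage")
}

#' Heatmap of precursor length vs highest-fragment length
#'
#' @param lib A cleaned [speclib()] (or a matrix from
#'   [length_cooccurrence()]).
#' @return A ggplot.
#' @export
plot_length_cooccurrence <- function(lib) {
  m <- if (is.matrix(lib)) lib else length_cooccurrence(lib)
  matrix_tile_plot(m, "highest-fragment length", "precursor length",
                   "Highest-fragment length by precursor length")
}
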