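# Simplified peptide-spectrum-match test: group peptides by similar
# precursor m/z sharing several similar fragment m/z, then check whether the
# predicted spectrum identifies its own peptide within the group.

# number of values in `a` that have at least one value of `b` within tol
count_shared_mz <- function(a, b, tol) {
  b <- sort(b)
  lo <- findInterval(a - tol, b)
  hi <- findInterval(a + tol, b)
  sum(hi > lo)
}

#' Group peptides by shared precursor and fragment m/z
#'
#' Two peptides are linked when their precursor m/z differ by at most
#' `precursor_tol` and at least `min_shared` of one peptide's product ions
#' have a counterpart within `fragment_tol` in the other. Groups are the
#' connected components of this link graph; singleton components are
#' dropped. The partition is invariant to library order (only the group
#' labels change).
#'
#' @param lib A cleaned [speclib()] with annotated peak m/z.
#' @param precursor_tol Precursor tolerance in Th (default 0.5).
#' @param fragment_tol Fragment tolerance in Th (default 0.5).
#' @param min_shared Minimum matched product ions (default 3).
#' @return A tibble (`peptide_id`, `group_id`, `sequence`,
#'   `precursor_charge`) covering peptides in groups of size >= 2.
#' @export
psm_grouping <- function(lib, precursor_tol = 0.5, fragment_tol = 0.5,
                         min_shared = 3L) {
  n <- nrow(lib)
  if (n < 2L) {
    return(tibble::tibble(peptide_id = integer(), group_id = integer(),
                          sequence = character(), precursor_charge = integer()))
  }
  premz <- vapply(seq_len(n), function(i)
    precursor_mz(lib$sequence[i], lib$precursor_charge[i]), numeric(1))
  frag <- lapply(lib$peaks, `[[`, "mz")

  ord <- order(premz)
  edges <- list(); ne <- 0L
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (premz[j] - premz[i] > precursor_tol) break
      if (count_shared_mz(frag[[i]], frag[[j]], fragment_tol) >= min_shared ||
          count_shared_mz(frag[[j]], frag[[i]], fragment_tol) >= min_shared) {
        ne <- ne + 1L
        edges[[ne]] <- c(i, j)
      }
    }
  }
  if (!ne) {
    return(tibble::tibble(peptide_id = integer(), group_id = integer(),
                          sequence = character(), precursor_charge = integer()))
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  keep <- comp %in% which(tabulate(comp) >= 2L)
  ids <- which(keep)
  # stable labels: renumber components by their smallest member
  first <- tapply(ids, comp[ids], min)
  relabel <- stats::setNames(rank(first), names(first))
  tibble::tibble(peptide_id = ids,
                 group_id = as.integer(relabel[as.character(comp[ids])]),
                 sequence = lib$sequence[ids],
                 precursor_charge = lib$precursor_charge[ids])
}

#' PSM match accuracy within groups
#'
#' For each grouped peptide, its predicted spectrum is scored against the
#' database spectra of every member of its group; the best match is the
#' database spectrum with the highest Pearson correlation, ties broken by
#' the lowest mean squared error (both computed over the candidate's
#' feasible slots, zero-filled). The accuracy is the fraction of peptides
#' whose best match is themselves.
#'
#' @param pred `N x 42` prediction matrix aligned to the library rows.
#' @param groups Output of [psm_grouping()].
#' @param ds Encoded dataset for the same library ([encode_library()]), or
#'   the [speclib()] itself.
#' @return Fraction in `[0, 1]`.
#' @export
psm_match_accuracy <- function(pred, groups, ds) {
  if (inherits(ds, "speclib")) ds <- encode_library(ds)
  if (!nrow(groups)) return(NA_real_)
  correct <- logical(nrow(groups))
  for (r in seq_len(nrow(groups))) {
    i <- groups$peptide_id[r]
    members <- groups$peptide_id[groups$group_id == groups$group_id[r]]
    if (length(members) < 2L) next
    best_j <- NA_integer_; best_pcc <- -Inf; best_mse <- Inf
    for (j in members) {
      slots <- which(ds$mask[j, ])
      r_pcc <- pcc(pred[i, slots], ds$target[j, slots])
      if (is.na(r_pcc)) r_pcc <- -Inf
      r_mse <- mean((pred[i, slots] - ds$target[j, slots])^2)
      if (r_pcc > best_pcc || (r_pcc == best_pcc && r_mse < best_mse)) {
        best_j <- j; best_pcc <- r_pcc; best_mse <- r_mse
      }
    }
    correct[r] <- identical(best_j, i)
  }
  mean(correct)
}
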