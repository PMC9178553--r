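test_that("pcc matches the textbook covariance computation", {
  expect_equal(pcc(1:5, 1:5), 1)
  expect_equal(pcc(1:5, -(1:5)), -1)
  expect_true(is.na(pcc(rep(1, 5), 1:5)))
  expect_error(pcc(1:4, 1:5), "equal length")
  withr::with_seed(51L, {
    for (i in 1:20) {
      x <- rnorm(10); y <- rnorm(10)
      manual <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(pcc(x, y), manual, tolerance = 1e-12)
    }
  })
})

test_that("without-zero restricts to database peaks, with-zero to feasible slots", {
  spec <- speclib(sequence = "ACDEFGHIK", precursor_charge = 2L,
                  collision_energy = 30,
                  peaks = list(toy_peaks(c(8L, 7L, 6L, 5L), rep(1L, 4),
                                         c(0.9, 1, 0.5, 0.2),
                                         sequence = "ACDEFGHIK")),
                  source = "x")
  enc <- encode_targets(spec)
  pred <- runif(42)
  slots <- slot_of(c(8L, 7L, 6L, 5L), rep(1L, 4))
  expect_equal(pcc_without_zero(pred, spec),
               pcc(pred[slots], c(0.9, 1, 0.5, 0.2)))
  # perfect prediction on database slots
  perfect <- numeric(42); perfect[slots] <- c(0.9, 1, 0.5, 0.2)
  expect_equal(pcc_without_zero(perfect, spec), 1)

  wz_slots <- which(enc$mask)
  expect_equal(length(wz_slots), 16L)
  expect_gte(length(wz_slots), length(slots))
  expect_equal(pcc_with_zero(pred, spec), pcc(pred[wz_slots], enc$target[wz_slots]))

  # fewer than two database peaks: flagged missing
  one <- speclib("ACDEFGHIK", 2L, 30,
                 list(toy_peaks(5L, 1L, 1, sequence = "ACDEFGHIK")), "x")
  expect_true(is.na(pcc_without_zero(pred, one)))
})

test_that("with- and without-zero agree exactly when every feasible slot has a peak", {
  # charge-1 precursor: feasible slots are y1..y(L-1) at z = 1 only, and a
  # spectrum with all of them present makes the two correlations identical
  full <- speclib("ACDEFGHIK", 1L, 30,
                  peaks = list(toy_peaks(1:8, rep(1L, 8),
                                         c(5, 3, 8, 1, 9, 2, 7, 4) / 9,
                                         sequence = "ACDEFGHIK")),
                  source = "x")
  withr::with_seed(52L, {
    pred <- runif(42)
    expect_equal(pcc_without_zero(pred, full), pcc_with_zero(pred, full))

    # drop two peaks: the two correlations now run over different slot sets
    partial <- full
    partial$peaks[[1]] <- partial$peaks[[1]][1:6, ]
    expect_false(isTRUE(all.equal(pcc_without_zero(pred, partial),
                                  pcc_with_zero(pred, partial))))
  })
})

test_that("highest-peak accuracies match a brute-force oracle", {
  lib <- clean_library(simulate_library(simulator_params(n_peptides = 80L, seed = 14L)))
  lib <- lib[seq_len(min(50L, nrow(lib))), ]
  ds <- encode_library(lib)
  n <- n_samples(ds)
  expect_equal(unlist(highest_peak_accuracy(ds$target, ds)),
               c(accuracy_highest = 1, accuracy_top1of3 = 1, accuracy_top2of3 = 1))

  withr::with_seed(53L, {
    pred <- matrix(runif(n * 42), n)
    acc <- highest_peak_accuracy(pred, ds)
    hit1 <- hit13 <- hit23 <- logical(n)
    for (i in seq_len(n)) {
      feas <- which(ds$mask[i, ])
      pr <- feas[order(-pred[i, feas], feas)]
      present <- feas[ds$target[i, feas] > 0]
      db <- present[order(-ds$target[i, present], present)]
      db3 <- db[seq_len(min(3, length(db)))]
      hit1[i] <- pr[1] == db3[1]
      hit13[i] <- pr[1] %in% db3
      hit23[i] <- all(pr[1:2] %in% db3)
    }
    expect_equal(acc$accuracy_highest, mean(hit1))
    expect_equal(acc$accuracy_top1of3, mean(hit13))
    expect_equal(acc$accuracy_top2of3, mean(hit23))
    expect_lte(acc$accuracy_highest, acc$accuracy_top1of3)
  })

  # prediction argmax at the database 2nd-highest: top1of3 but not highest
  spec <- speclib("ACDEFGHIK", 2L, 30,
                  list(toy_peaks(c(5L, 6L), c(1L, 1L), c(1, 0.8),
                                 sequence = "ACDEFGHIK")), "x")
  dsp <- encode_library(spec)
  pred1 <- matrix(0, 1, 42); pred1[1, slot_of(6L, 1L)] <- 1
  acc1 <- highest_peak_accuracy(pred1, dsp)
  expect_equal(acc1$accuracy_highest, 0)
  expect_equal(acc1$accuracy_top1of3, 1)
})

test_that("psm grouping follows both tolerances and matches brute force", {
  # two peptides sharing three close fragments, precursors within 0.3 Th
  a <- "AAAGGSSK"
  b <- "AAAGGSTK"  # S->T shifts precursor by ~14; craft via charge instead
  lib <- speclib(sequence = c(a, a), precursor_charge = c(2L, 2L),
                 collision_energy = 30,
                 peaks = list(toy_peaks(c(2L, 3L, 4L), sequence = a),
                              toy_peaks(c(2L, 3L, 4L), sequence = a)),
                 source = "x")
  grp <- psm_grouping(lib)
  expect_equal(nrow(grp), 2L)
  expect_equal(grp$group_id, c(1L, 1L))

  # precursor difference above tolerance: never grouped
  lib2 <- speclib(sequence = c("AAAGGSSK", "AAAGGSSR"), precursor_charge = 2L,
                  collision_energy = 30,
                  peaks = list(toy_peaks(c(2L, 3L, 4L), sequence = "AAAGGSSK"),
                               toy_peaks(c(2L, 3L, 4L), sequence = "AAAGGSSR")),
                  source = "x")
  expect_equal(nrow(psm_grouping(lib2)), 0L)

  # brute-force all-pairs oracle on a simulated library
  lib3 <- clean_library(simulate_library(simulator_params(n_peptides = 120L, seed = 15L)))
  grp3 <- psm_grouping(lib3)
  premz <- vapply(seq_len(nrow(lib3)), function(i)
    precursor_mz(lib3$sequence[i], lib3$precursor_charge[i]), numeric(1))
  linked <- function(i, j) {
    if (abs(premz[i] - premz[j]) > 0.5) return(FALSE)
    shared_ij <- sum(vapply(lib3$peaks[[i]]$mz, function(m)
      any(abs(lib3$peaks[[j]]$mz - m) <= 0.5), logical(1)))
    shared_ji <- sum(vapply(lib3$peaks[[j]]$mz, function(m)
      any(abs(lib3$peaks[[i]]$mz - m) <= 0.5), logical(1)))
    max(shared_ij, shared_ji) >= 3
  }
  n3 <- nrow(lib3)
  adj <- matrix(FALSE, n3, n3)
  for (i in seq_len(n3 - 1)) for (j in (i + 1):n3) {
    adj[i, j] <- adj[j, i] <- linked(i, j)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  keep <- comp$membership %in% which(comp$csize >= 2)
  expect_equal(sort(grp3$peptide_id), which(keep))
  if (nrow(grp3)) {
    # identical partitions (compare as sets of member sets)
    ours <- split(grp3$peptide_id, grp3$group_id)
    theirs <- split(which(keep), comp$membership[keep])
    expect_setequal(vapply(ours, paste, character(1), collapse = ","),
                    vapply(theirs, paste, character(1), collapse = ","))
  }
})

test_that("psm match accuracy is 1 for perfect predictions and penalizes swaps", {
  lib <- speclib(sequence = c("AAAGGSSK", "AAAGGSSK"), precursor_charge = c(2L, 2L),
                 collision_energy = 30,
                 peaks = list(toy_peaks(c(2L, 3L, 4L), intensities = c(1, 0.5, 0.2),
                                        sequence = "AAAGGSSK"),
                              toy_peaks(c(2L, 3L, 5L), intensities = c(0.3, 1, 0.6),
                                        sequence = "AAAGGSSK")),
                 source = "x")
  lib$sequence[2] <- "AAAGGSSK"  # same precursor; different spectra
  ds <- encode_library(lib)
  groups <- tibble::tibble(peptide_id = c(1L, 2L), group_id = c(1L, 1L),
                           sequence = lib$sequence,
                           precursor_charge = lib$precursor_charge)
  expect_equal(psm_match_accuracy(ds$target, groups, ds), 1)
  # swap predictions: each best-matches the other spectrum
  swapped <- ds$target[c(2, 1), ]
  expect_equal(psm_match_accuracy(swapped, groups, ds), 0)
})

test_that("evaluate_model produces a coherent report", {
  lib <- clean_library(simulate_library(simulator_params(n_peptides = 40L, seed = 16L)))
  m <- random_params_model()
  rep <- evaluate_model(m, lib, psm = FALSE)
  expect_s3_class(rep, "yfrag_eval")
  expect_equal(nrow(rep$per_peptide), nrow(lib))
  expect_true(all(unlist(rep[c("accuracy_highest", "accuracy_top1of3",
                               "accuracy_top2of3")]) >= 0))
  expect_true(rep$median_pcc_without_zero >= -1 &&
                rep$median_pcc_without_zero <= 1)
  gl <- glance(rep)
  expect_equal(gl$n_peptides, nrow(lib))
  expect_equal(tidy(rep), rep$per_peptide)
})
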