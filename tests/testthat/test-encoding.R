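test_that("slot index is a bijection over the 42 (ordinal, charge) pairs", {
  slots <- integer(0)
  for (k in 1:14) for (z in 1:3) slots <- c(slots, slot_of(k, z))
  expect_equal(sort(slots), 1:42)
  back <- ion_of(slot_of(rep(1:14, each = 3), rep(1:3, 14)))
  expect_equal(back$ordinal, rep(1:14, each = 3))
  expect_equal(back$fragment_charge, rep(1:3, 14))
})

test_that("one-hot encoding follows the 20-letter alphabetical layout", {
  m <- one_hot_sequence("AAAAAA")
  expect_equal(dim(m), c(15L, 20L))
  expect_equal(unname(m[1:6, 1]), rep(1, 6))
  expect_equal(sum(m), 6)
  expect_equal(rowSums(m)[7:15], stats::setNames(rep(0, 9), NULL))

  m2 <- one_hot_sequence("ACDEFGHIKLMNPQR")
  expect_equal(rowSums(m2), rep(1, 15))
  expect_equal(unname(which(m2[3, ] == 1)), match("D", aa_alphabet()))

  expect_error(one_hot_sequence("AAAA"), "length 4")
  expect_error(one_hot_sequence("AAAAAAAAAAAAAAAA"), "length 16")
  expect_error(one_hot_sequence("AAAAAB"), "non-canonical")
})

test_that("scalar features count length and prolines", {
  f <- scalar_features("PEPTIDEK", 2L, 30, standardize = FALSE)
  expect_equal(unname(f), c(30, 2, 8, 2))
  expect_equal(unname(scalar_features("ELVISK", 2L, 30, standardize = FALSE)["prolines"]), 0)
  fs <- scalar_features("PEPTIDEK", 2L, 30)
  expect_equal(unname(fs), c(30 / 100, 2 / 3, 8 / 15, 2 / 15))
  # NA collision energy falls back to the default
  expect_equal(unname(scalar_features("PEPTIDEK", 2L, NA, standardize = FALSE)["ce"]), 30)

  withr::with_seed(4L, {
    for (i in 1:50) {
      L <- sample(6:15, 1)
      s <- paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
      f <- scalar_features(s, 2L, 30, standardize = FALSE)
      expect_equal(unname(f["length"]), L)
      expect_equal(unname(f["prolines"]),
                   sum(strsplit(s, "")[[1]] == "P"))
    }
  })
})

test_that("sliding windows fill length - 3 columns and pad the rest", {
  m15 <- sliding_windows(strrep("A", 15))
  expect_equal(dim(m15), c(4L, 12L))
  expect_true(all(m15 == 1 / 20))          # 'A' codes in all 12 columns

  m6 <- sliding_windows("ACDEFG")
  expect_equal(sum(colSums(m6) > 0), 3L)   # 6 - 4 + 1 populated columns
  expect_equal(m6[, 1], match(c("A", "C", "D", "E"), aa_alphabet()) / 20)
  expect_equal(m6[, 4:12], matrix(0, 4, 9))

  oh <- sliding_windows("ACDEFG", onehot = TRUE)
  expect_equal(dim(oh), c(80L, 12L))
  expect_equal(colSums(oh), c(4, 4, 4, rep(0, 9)))
})

test_that("feasibility mask implements the length and charge rules", {
  # a 14-residue fragment cannot come from a length-8 peptide
  m8 <- feasibility_mask(8L, 3L)
  expect_false(any(m8[slot_of(rep(14L, 3), 1:3)]))
  expect_false(any(m8[slot_of(rep(8L, 3), 1:3)]))
  expect_true(all(m8[slot_of(rep(7L, 3), 1:3)]))

  # length 9 at charge 2: y1..y8 at z 1..2 feasible, 16 slots
  m9 <- feasibility_mask(9L, 2L)
  expect_equal(sum(m9), 16L)
  expect_true(all(m9[slot_of(rep(1:8, each = 2), rep(1:2, 8))]))

  expect_equal(sum(feasibility_mask(15L, 3L)), 42L)
  expect_error(feasibility_mask(5L, 2L), "length")
  expect_error(feasibility_mask(9L, 4L), "charge")

  # monotone: growing length or charge never removes feasible slots
  for (L in 6:14) {
    expect_true(all(feasibility_mask(L, 2L) <= feasibility_mask(L + 1L, 2L)))
  }
  for (z in 1:2) {
    expect_true(all(feasibility_mask(10L, z) <= feasibility_mask(10L, z + 1L)))
  }
})

test_that("target encoding matches the length-9 charge-2 worked example", {
  spec <- speclib(sequence = "ACDEFGHIK", precursor_charge = 2L,
                  collision_energy = 30,
                  peaks = list(toy_peaks(c(8L, 7L, 6L, 5L), rep(1L, 4),
                                         c(0.9, 1, 0.5, 0.2),
                                         sequence = "ACDEFGHIK")),
                  source = "x")
  enc <- encode_targets(spec)
  expect_equal(sum(enc$target > 0), 4L)
  expect_equal(sum(enc$target == 0), 12L)
  expect_equal(sum(enc$target == -1), 26L)
  expect_equal(enc$target[slot_of(7L, 1L)], 1)        # base peak
  expect_equal(enc$target[slot_of(8L, 1L)], 0.9)
  expect_equal(enc$target == -1, !enc$mask)
})

test_that("base-peak normalization and infeasible-peak errors hold", {
  single <- speclib("PEPTIDEK", 2L, 30, list(toy_peaks(4L, 1L, 0.37,
                                                       sequence = "PEPTIDEK")), "x")
  expect_equal(max(encode_targets(single)$target), 1)

  bad <- speclib("PEPTIDEK", 2L, 30, list(toy_peaks(4L, 3L, 1,
                                                    sequence = "PEPTIDEK")), "x")
  expect_error(encode_targets(bad), "y4\\^3")
})

test_that("encode/decode round trip recovers simulated peak sets", {
  lib <- clean_library(simulate_library(simulator_params(n_peptides = 80L, seed = 5L)))
  for (i in seq_len(nrow(lib))) {
    enc <- encode_targets(lib[i, ])
    dec <- decode_targets(enc$target, nchar(lib$sequence[i]),
                          lib$precursor_charge[i])
    pk <- lib$peaks[[i]]
    expect_equal(
      dec[order(dec$ordinal, dec$fragment_charge), c("ordinal", "fragment_charge")],
      pk[order(pk$ordinal, pk$fragment_charge), c("ordinal", "fragment_charge")],
      ignore_attr = TRUE)
    expect_equal(sort(dec$intensity), sort(pk$intensity / max(pk$intensity)))
  }
})

test_that("decode_targets orders by intensity with slot-order ties", {
  v <- rep(-1, 42)
  m <- feasibility_mask(10L, 2L)
  v[m] <- 0
  v[slot_of(3L, 1L)] <- 0.5
  v[slot_of(5L, 1L)] <- 0.5
  v[slot_of(2L, 1L)] <- 1
  dec <- decode_targets(v, 10L, 2L)
  expect_equal(dec$ordinal, c(2L, 3L, 5L))
  expect_equal(nrow(decode_targets(ifelse(m, 0, -1), 10L, 2L)), 0L)
  expect_error(decode_targets(numeric(10), 10L, 2L), "length 42")
})

test_that("encoded tables round trip through CSV bit-exactly", {
  lib <- clean_library(simulate_library(simulator_params(n_peptides = 15L, seed = 9L)))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_encoded(lib, tf)
  back <- read_encoded(tf)
  expect_equal(back$sequence, lib$sequence)
  for (i in seq_len(nrow(lib))) {
    enc <- encode_targets(lib[i, ])
    expect_identical(unname(back$target[i, ]), enc$target)
    expect_identical(unname(back$mask[i, ]), enc$mask)
  }
})
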