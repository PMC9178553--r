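# Shared fixtures: tiny handmade libraries and small model configurations.

toy_peaks <- function(ordinals, charges = rep(1L, length(ordinals)),
                      intensities = seq_along(ordinals), series = "y",
                      sequence = NULL) {
  mz <- if (!is.null(sequence)) {
    vapply(seq_along(ordinals), function(i)
      yfrag::y_ion_mz(sequence, ordinals[i], charges[i]), numeric(1))
  } else {
    100 + 50 * ordinals / charges
  }
  tibble::tibble(series = series, ordinal = as.integer(ordinals),
                 fragment_charge = as.integer(charges), mz = mz,
                 intensity = as.numeric(intensities))
}

toy_library <- function() {
  speclib(
    sequence = c("PEPTIDEK", "ELVISLIVE", "ACDEFGHIK"),
    precursor_charge = c(2L, 2L, 3L),
    collision_energy = c(30, 25.5, NA),
    peaks = list(
      toy_peaks(c(3L, 5L), c(1L, 2L), c(0.5, 1), sequence = "PEPTIDEK"),
      toy_peaks(c(2L, 4L, 6L), c(1L, 1L, 2L), c(1, 0.25, 0.5), sequence = "ELVISLIVE"),
      toy_peaks(c(1L, 4L, 7L), c(1L, 1L, 3L), c(0.2, 1, 0.7), sequence = "ACDEFGHIK")
    ),
    source = "toy"
  )
}

# deliberately small architecture: fast enough for unit tests
tiny_model_config <- function(seed = 1L, ...) {
  do.call(model_config, utils::modifyList(
    list(hidden_size = 8L, fcn_hidden = c(8L, 8L), cnn_channels = c(2L, 3L, 4L),
         cnn_out = 6L, dec_dim = 6L, head_hidden = 12L, dropout = 0,
         seed = seed),
    list(...)))
}

random_params_model <- function(config = tiny_model_config(), seed = 99L) {
  m <- build_model(config)
  withr::with_seed(seed, {
    m$params <- lapply(m$params, function(p) {
      p[] <- stats::rnorm(length(p), sd = 0.2)
      p
    })
  })
  m
}

small_encoded <- function(n = 6L, seed = 21L) {
  lib <- clean_library(simulate_library(simulator_params(
    n_peptides = as.integer(ceiling(n * 1.6)), seed = seed)))
  encode_library(lib[seq_len(min(n, nrow(lib))), ])
}
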