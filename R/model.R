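# The intensity-prediction network: a bidirectional GRU encoder over the
# one-hot sequence with dot-product attention, a dense path for the scalar
# features, a three-layer CNN for the 4 x 12 sliding-window matrix, a
# bilinear merge of encoder states with the combined feature vector, a GRU
# decoder with a second attention layer, and a linear head that emits the 42
# y-ion intensity slots.

#' Model configuration
#'
#' @param hidden_size GRU hidden width per direction (default 128).
#' @param fcn_hidden Widths of the dense layers on the scalar features.
#' @param cnn_channels Channel counts of the three convolution layers.
#' @param cnn_out Width of the CNN projection after flattening.
#' @param dec_dim Width of the merged decoder input.
#' @param head_hidden Width of the hidden prediction layer.
#' @param dropout Dropout probability after the second attention layer
#'   (training only).
#' @param max_length Maximum peptide length (one-hot rows; default 15).
#' @param seed Seed for parameter initialization; fixing it makes builds
#'   bit-reproducible.
#' @return A `ModelConfig` list.
#' @export
model_config <- function(hidden_size = 128L, fcn_hidden = c(32L, 32L),
                         cnn_channels = c(16L, 32L, 64L), cnn_out = 32L,
                         dec_dim = 32L, head_hidden = 64L, dropout = 0.1,
                         max_length = MAX_PEP_LENGTH, seed = 1L) {
  stopifnot(hidden_size > 0, dropout >= 0, dropout < 1,
            length(cnn_channels) == 3L)
  structure(list(hidden_size = as.integer(hidden_size),
                 fcn_hidden = as.integer(fcn_hidden),
                 cnn_channels = as.integer(cnn_channels),
                 cnn_out = as.integer(cnn_out), dec_dim = as.integer(dec_dim),
                 head_hidden = as.integer(head_hidden), dropout = dropout,
                 max_length = as.integer(max_length),
                 output_dim = N_SLOTS, seed = as.integer(seed)),
            class = "yfrag_config")
}

#' Desk-scale experiment configuration
#'
#' The reduced architecture used throughout the package's simulated
#' experiments: GRU hidden size 32, a lean CNN (4/8/8 channels projected to
#' 16), 16-wide dense layers, and no dropout. Paired with
#' [desk_train_config()] (30 epochs, batch 128) it trains in about a minute
#' per fold on one CPU while recovering the simulator's structure.
#'
#' @param seed Parameter-initialization seed.
#' @param ... Overrides passed to [model_config()].
#' @return A [model_config()].
#' @export
desk_model_config <- function(seed = 1L, ...) {
  do.call(model_config, utils::modifyList(
    list(hidden_size = 32L, cnn_channels = c(4L, 8L, 8L), cnn_out = 16L,
         fcn_hidden = c(16L, 16L), head_hidden = 64L, dec_dim = 64L,
         dropout = 0, seed = seed),
    list(...)))
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a predictor from a configuration
#'
#' Parameters are initialized deterministically from `config$seed`: two
#' builds with the same configuration have identical parameters and produce
#' identical outputs.
#'
#' @param config A [model_config()].
#' @return A `yfrag_model` (configuration + named parameter list).
#' @export
build_model <- function(config = model_config()) {
  H <- config$hidden_size
  cc <- config$cnn_channels
  geoms <- list(
    conv_geom(4L, 12L, 1L,   cc[1]),
    conv_geom(4L, 12L, cc[1], cc[2]),
    conv_geom(4L, 12L, cc[2], cc[3])
  )
  fcn_last <- utils::tail(config$fcn_hidden, 1L)
  Fdim <- fcn_last + config$cnn_out

  params <- withr::with_seed(config$seed, {
    p <- list(
      enc_f_Wx = glorot(20L, 3L * H), enc_f_Wh = glorot(H, 3L * H),
      enc_f_bx = numeric(3L * H),     enc_f_bh = numeric(3L * H),
      enc_b_Wx = glorot(20L, 3L * H), enc_b_Wh = glorot(H, 3L * H),
      enc_b_bx = numeric(3L * H),     enc_b_bh = numeric(3L * H)
    )
    d_in <- 4L
    for (i in seq_along(config$fcn_hidden)) {
      p[[sprintf("fcn_W%d", i)]] <- glorot(d_in, config$fcn_hidden[i])
      p[[sprintf("fcn_b%d", i)]] <- numeric(config$fcn_hidden[i])
      d_in <- config$fcn_hidden[i]
    }
    for (i in 1:3) {
      p[[sprintf("cnn_K%d", i)]] <- glorot(geoms[[i]]$inner, geoms[[i]]$cout)
      p[[sprintf("cnn_b%d", i)]] <- numeric(geoms[[i]]$cout)
    }
    p$cnn_proj_W <- glorot(geoms[[3]]$n_out, config$cnn_out)
    p$cnn_proj_b <- numeric(config$cnn_out)
    p$merge_Wm <- glorot(2L * H, config$dec_dim)
    p$merge_bm <- numeric(config$dec_dim)
    p$merge_Wg <- glorot(Fdim, config$dec_dim)
    p$merge_bg <- numeric(config$dec_dim)
    p$dec0_W <- glorot(4L * H, H)
    p$dec0_b <- numeric(H)
    p$dec_Wx <- glorot(config$dec_dim, 3L * H)
    p$dec_Wh <- glorot(H, 3L * H)
    p$dec_bx <- numeric(3L * H)
    p$dec_bh <- numeric(3L * H)
    # site readout: shared network over the two decoder states flanking a
    # cleavage, plus a per-ordinal output layer emitting the three charge
    # slots of that fragment length
    p$head_W1 <- glorot(3L * H + Fdim, config$head_hidden)
    p$head_b1 <- numeric(config$head_hidden)
    for (k in seq_len(MAX_ORDINAL)) {
      p[[sprintf("head_Wk%02d", k)]] <- glorot(config$head_hidden, 3L)
      p[[sprintf("head_bk%02d", k)]] <- numeric(3L)
    }
    p
  })
  structure(list(config = config, params = params, geoms = geoms),
            class = "yfrag_model")
}

#' @export
print.yfrag_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("# y-ion intensity model: hidden %d, %s parameters\n",
              x$config$hidden_size, format(np, big.mark = ",")))
  invisible(x)
}

# Builds the computation graph for one batch; returns tape, output node and
# the parameter nodes (for gradient collection).
model_graph <- function(model, ds, training = FALSE) {
  cfg <- model$config
  H <- cfg$hidden_size
  Lmax <- cfg$max_length
  B <- n_samples(ds)
  tp <- tape_new()
  pn <- lapply(model$params, function(v) nd_param(tp, v))

  lens <- ds$meta$length
  # y ions are indexed from the C terminus, so the sequence is anchored
  # there: residues are right-aligned onto the Lmax rows (padding first).
  # Each cleavage site then sits at a length-independent position.
  aligned <- array(0, dim = c(B, Lmax, 20L))
  for (i in seq_len(B)) {
    aligned[i, (Lmax - lens[i] + 1L):Lmax, ] <- ds$onehot[i, seq_len(lens[i]), ]
  }
  key_mask <- outer(Lmax - lens, seq_len(Lmax), "<")
  x_t <- lapply(seq_len(Lmax), function(t)
    nd_const(tp, matrix(aligned[, t, ], nrow = B, ncol = 20L)))

  zero_h <- nd_const(tp, matrix(0, B, H))
  states_f <- vector("list", Lmax)
  h <- zero_h
  for (t in seq_len(Lmax)) {
    h <- nd_gru_step(tp, x_t[[t]], h, pn$enc_f_Wx, pn$enc_f_Wh,
                     pn$enc_f_bx, pn$enc_f_bh, mask = as.numeric(key_mask[, t]))
    states_f[[t]] <- h
  }
  states_b <- vector("list", Lmax)
  h <- zero_h
  for (t in rev(seq_len(Lmax))) {
    h <- nd_gru_step(tp, x_t[[t]], h, pn$enc_b_Wx, pn$enc_b_Wh,
                     pn$enc_b_bx, pn$enc_b_bh, mask = as.numeric(key_mask[, t]))
    states_b[[t]] <- h
  }
  enc_states <- lapply(seq_len(Lmax), function(t)
    nd_cbind(tp, list(states_f[[t]], states_b[[t]])))
  enc_final <- nd_cbind(tp, list(states_f[[Lmax]], states_b[[1]]))
  ctx1 <- nd_attention(tp, enc_final, enc_states, key_mask)

  # scalar-feature path
  f <- nd_const(tp, ds$features)
  for (i in seq_along(cfg$fcn_hidden)) {
    f <- nd_relu(tp, nd_linear(tp, f, pn[[sprintf("fcn_W%d", i)]],
                               pn[[sprintf("fcn_b%d", i)]]))
  }

  # sliding-window CNN path; window columns are right-aligned like the
  # sequence so that a column's distance from the right edge tracks the
  # cleavage distance from the C terminus
  wins <- array(0, dim = dim(ds$windows))
  nwin <- pmin(lens - 3L, 12L)
  for (i in seq_len(B)) {
    wins[i, , (12L - nwin[i] + 1L):12L] <- ds$windows[i, , seq_len(nwin[i])]
  }
  cx <- nd_const(tp, matrix(wins, nrow = B, ncol = 48L))
  for (i in 1:3) {
    cx <- nd_relu(tp, nd_conv2d(tp, cx, pn[[sprintf("cnn_K%d", i)]],
                                pn[[sprintf("cnn_b%d", i)]], model$geoms[[i]]))
  }
  cx <- nd_relu(tp, nd_linear(tp, cx, pn$cnn_proj_W, pn$cnn_proj_b))

  # bilinear merge of encoder states with the combined feature vector
  feat <- nd_cbind(tp, list(f, cx))
  gate <- nd_linear(tp, feat, pn$merge_Wg, pn$merge_bg)

  s <- nd_tanh(tp, nd_linear(tp, nd_cbind(tp, list(enc_final, ctx1)),
                             pn$dec0_W, pn$dec0_b))
  dec_states <- vector("list", Lmax)
  for (t in seq_len(Lmax)) {
    u <- nd_mul(tp, nd_linear(tp, enc_states[[t]], pn$merge_Wm, pn$merge_bm), gate)
    s <- nd_gru_step(tp, u, s, pn$dec_Wx, pn$dec_Wh, pn$dec_bx, pn$dec_bh,
                     mask = as.numeric(key_mask[, t]))
    dec_states[[t]] <- s
  }
  ctx2 <- nd_attention(tp, s, dec_states, key_mask)
  ctx2 <- nd_dropout(tp, ctx2, cfg$dropout, training)

  # position-tied readout: with the sequence anchored at the C terminus,
  # the cleavage producing y_k always sits between rows Lmax-k and
  # Lmax-k+1, so slot (k, z) reads the two decoder states flanking its own
  # cleavage (plus the attention context and feature vector) through a
  # shared site network and a per-ordinal linear output
  out <- nd_site_head(tp, dec_states, ctx2, feat, pn$head_W1, pn$head_b1,
                      lapply(sprintf("head_Wk%02d", seq_len(MAX_ORDINAL)),
                             function(nm) pn[[nm]]),
                      lapply(sprintf("head_bk%02d", seq_len(MAX_ORDINAL)),
                             function(nm) pn[[nm]]),
                      Lmax)
  list(tape = tp, out = out, pnodes = pn)
}

#' Forward pass
#'
#' @param model A `yfrag_model`.
#' @param ds A `yfrag_dataset` (see [encode_library()]).
#' @param training Apply dropout (default `FALSE`; evaluation mode is
#'   deterministic).
#' @return A `B x 42` matrix of predicted slot intensities (unclamped).
#' @export
forward <- function(model, ds, training = FALSE) {
  model_graph(model, ds, training = training)$out$value
}

#' Dot-product attention (reference implementation)
#'
#' Scaled dot-product attention with keys equal to values: scores are
#' `q . k / sqrt(d)`, softmax-normalized over key positions; the context is
#' the score-weighted sum of the keys.
#'
#' @param query Numeric vector of length d (one query).
#' @param keys `L x d` matrix of keys/values.
#' @return A list with `weights` (length L, sums to 1) and `context`
#'   (length d).
#' @export
dot_attention <- function(query, keys) {
  keys <- as.matrix(keys)
  if (length(query) != ncol(keys)) {
    stop("query length must match key dimension", call. = FALSE)
  }
  s <- as.numeric(keys %*% query) / sqrt(length(query))
  e <- exp(s - max(s))
  w <- e / sum(e)
  list(weights = w, context = as.numeric(t(w) %*% keys))
}

# ---- losses ---------------------------------------------------------------

#' Mean squared error loss
#'
#' The default follows the training recipe literally: the mean runs over all
#' 42 slots, including those filled with -1. With `mask_infeasible = TRUE`
#' the infeasible slots are excluded from the mean.
#'
#' @param prediction,target `B x 42` matrices (or vectors of length 42).
#' @param mask Logical matrix of feasible slots; required when
#'   `mask_infeasible` is set.
#' @param mask_infeasible Exclude infeasible (-1) slots.
#' @return A single non-negative number.
#' @export
loss_mse <- function(prediction, target, mask = NULL, mask_infeasible = FALSE) {
  prediction <- rbind(prediction); target <- rbind(target)
  if (mask_infeasible) {
    if (is.null(mask)) stop("`mask` is required when `mask_infeasible`", call. = FALSE)
    w <- rbind(mask) * 1
  } else {
    w <- matrix(1, nrow(prediction), ncol(prediction))
  }
  sum(w * (prediction - target)^2) / sum(w)
}

topk_weight_matrix <- function(target, mask = NULL, k = 3L) {
  target <- rbind(target)
  w <- matrix(0, nrow(target), ncol(target))
  for (i in seq_len(nrow(target))) {
    cand <- if (is.null(mask)) seq_len(ncol(target)) else which(rbind(mask)[i, ])
    ki <- k
    if (ki > length(cand)) {
      warning(sprintf("k = %d exceeds %d candidate slots; clipped", k, length(cand)),
              call. = FALSE)
      ki <- length(cand)
    }
    top <- cand[order(-target[i, cand], cand)[seq_len(ki)]]
    w[i, top] <- 1
  }
  w
}

#' Top-k weighted loss
#'
#' [loss_mse()] plus `weight` times the mean squared error restricted to
#' each sample's `k` highest-target slots — the altered objective that puts
#' extra emphasis on the most intense fragments.
#'
#' @inheritParams loss_mse
#' @param k Number of highest-target slots (default 3).
#' @param weight Weight of the top-k term.
#' @return A single non-negative number.
#' @export
loss_topk_weighted <- function(prediction, target, mask = NULL, k = 3L,
                               weight = 0.5) {
  base <- loss_mse(prediction, target, mask = mask, mask_infeasible = !is.null(mask))
  w <- topk_weight_matrix(target, mask, k)
  prediction <- rbind(prediction); target <- rbind(target)
  base + weight * sum(w * (prediction - target)^2) / sum(w)
}

#' Save / load a model checkpoint
#'
#' The checkpoint file stores the configuration, every parameter and the
#' seed; [load_model()] reproduces forward outputs bit-exactly on the saving
#' platform.
#'
#' @param model A `yfrag_model`.
#' @param path Checkpoint path.
#' @return `load_model` returns the `yfrag_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  structure(readRDS(path), class = "yfrag_model")
}
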