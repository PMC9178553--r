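# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records nodes in creation order; backward() seeds the terminal
# gradient and replays the tape in reverse, each node accumulating into its
# parents. Layer-level operations (GRU step, dot-product attention, 2-D
# convolution, masked MSE) are fused single nodes with analytic gradients —
# all verified against central finite differences in the test suite.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

push_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

nd_const <- function(tape, value) push_node(tape, value)
nd_param <- function(tape, value) push_node(tape, value)

acc_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

backward <- function(tape, loss) {
  if (is.null(loss$grad)) loss$grad <- 1   # respect a pre-seeded gradient
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- elementwise and linear-algebra primitives -----------------------------

nd_add <- function(tape, a, b) {
  push_node(tape, a$value + b$value, list(a, b), function(nd) {
    acc_grad(nd$parents[[1]], nd$grad)
    acc_grad(nd$parents[[2]], nd$grad)
  })
}

nd_sub <- function(tape, a, b) {
  push_node(tape, a$value - b$value, list(a, b), function(nd) {
    acc_grad(nd$parents[[1]], nd$grad)
    acc_grad(nd$parents[[2]], -nd$grad)
  })
}

nd_mul <- function(tape, a, b) {
  push_node(tape, a$value * b$value, list(a, b), function(nd) {
    acc_grad(nd$parents[[1]], nd$grad * nd$parents[[2]]$value)
    acc_grad(nd$parents[[2]], nd$grad * nd$parents[[1]]$value)
  })
}

nd_axpy <- function(tape, a, b, wa = 1, wb = 1) {
  push_node(tape, wa * a$value + wb * b$value, list(a, b), function(nd) {
    acc_grad(nd$parents[[1]], wa * nd$grad)
    acc_grad(nd$parents[[2]], wb * nd$grad)
  })
}

nd_matmul <- function(tape, a, b) {
  push_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    acc_grad(nd$parents[[1]], tcrossprod(nd$grad, nd$parents[[2]]$value))
    acc_grad(nd$parents[[2]], crossprod(nd$parents[[1]]$value, nd$grad))
  })
}

# y = x W + b (bias a numeric vector, broadcast over rows)
nd_linear <- function(tape, x, W, b) {
  v <- x$value %*% W$value
  v <- v + rep(b$value, each = nrow(v))
  push_node(tape, v, list(x, W, b), function(nd) {
    x <- nd$parents[[1]]; W <- nd$parents[[2]]; b <- nd$parents[[3]]
    acc_grad(x, tcrossprod(nd$grad, W$value))
    acc_grad(W, crossprod(x$value, nd$grad))
    acc_grad(b, colSums(nd$grad))
  })
}

nd_relu <- function(tape, a) {
  push_node(tape, pmax(a$value, 0), list(a), function(nd) {
    acc_grad(nd$parents[[1]], nd$grad * (nd$parents[[1]]$value > 0))
  })
}

nd_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  nd <- push_node(tape, v, list(a), function(nd) {
    acc_grad(nd$parents[[1]], nd$grad * nd$value * (1 - nd$value))
  })
  nd
}

nd_tanh <- function(tape, a) {
  v <- tanh(a$value)
  push_node(tape, v, list(a), function(nd) {
    acc_grad(nd$parents[[1]], nd$grad * (1 - nd$value^2))
  })
}

nd_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  push_node(tape, do.call(cbind, lapply(nodes, `[[`, "value")), nodes, function(nd) {
    for (i in seq_along(nd$parents)) {
      acc_grad(nd$parents[[i]], nd$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

nd_dropout <- function(tape, a, p, training) {
  if (!training || p <= 0) return(a)
  keep <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= p) / (1 - p)
  push_node(tape, a$value * keep, list(a), function(nd) {
    acc_grad(nd$parents[[1]], nd$grad * keep)
  })
}

# ---- fused layers ----------------------------------------------------------

# One masked GRU step (torch gate convention). x: B x D, h: B x H,
# Wx: D x 3H, Wh: H x 3H, biases length 3H; gate order (r, z, n).
# mask: length-B 0/1 vector; rows with mask 0 keep their previous state.
nd_gru_step <- function(tape, x, h, Wx, Wh, bx, bh, mask = NULL) {
  H <- ncol(h$value)
  B <- nrow(h$value)
  ir <- seq_len(H); iz <- ir + H; inn <- iz + H
  gx <- x$value %*% Wx$value + rep(bx$value, each = B)
  gh <- h$value %*% Wh$value + rep(bh$value, each = B)
  r <- 1 / (1 + exp(-(gx[, ir, drop = FALSE] + gh[, ir, drop = FALSE])))
  z <- 1 / (1 + exp(-(gx[, iz, drop = FALSE] + gh[, iz, drop = FALSE])))
  ghn <- gh[, inn, drop = FALSE]
  n <- tanh(gx[, inn, drop = FALSE] + r * ghn)
  hnew <- (1 - z) * n + z * h$value
  hout <- if (is.null(mask)) hnew else hnew * mask + h$value * (1 - mask)

  push_node(tape, hout, list(x, h, Wx, Wh, bx, bh), function(nd) {
    x <- nd$parents[[1]]; h <- nd$parents[[2]]
    Wx <- nd$parents[[3]]; Wh <- nd$parents[[4]]
    bx <- nd$parents[[5]]; bh <- nd$parents[[6]]
    if (is.null(mask)) {
      dhnew <- nd$grad; dh <- 0
    } else {
      dhnew <- nd$grad * mask; dh <- nd$grad * (1 - mask)
    }
    dz <- dhnew * (h$value - n)
    dn <- dhnew * (1 - z)
    dh <- dh + dhnew * z
    dgn <- dn * (1 - n^2)
    dr <- dgn * ghn
    dghn <- dgn * r
    dgz <- dz * z * (1 - z)
    dgr <- dr * r * (1 - r)
    dgx <- cbind(dgr, dgz, dgn)
    dgh <- cbind(dgr, dgz, dghn)
    acc_grad(x, tcrossprod(dgx, Wx$value))
    acc_grad(Wx, crossprod(x$value, dgx))
    acc_grad(bx, colSums(dgx))
    acc_grad(h, dh + tcrossprod(dgh, Wh$value))
    acc_grad(Wh, crossprod(h$value, dgh))
    acc_grad(bh, colSums(dgh))
  })
}

# Scaled dot-product attention with keys == values. q: B x D, keys: list of
# L nodes (B x D). key_mask: B x L logical (FALSE = padded position).
nd_attention <- function(tape, q, keys, key_mask = NULL) {
  B <- nrow(q$value); L <- length(keys); D <- ncol(q$value)
  scale <- 1 / sqrt(D)
  S <- vapply(keys, function(k) rowSums(q$value * k$value) * scale, numeric(B))
  S <- matrix(S, nrow = B)
  if (!is.null(key_mask)) S[!key_mask] <- -1e30
  E <- exp(S - apply(S, 1L, max))
  W <- E / rowSums(E)
  ctx <- matrix(0, B, D)
  for (l in seq_len(L)) ctx <- ctx + W[, l] * keys[[l]]$value

  push_node(tape, ctx, c(list(q), keys), function(nd) {
    q <- nd$parents[[1]]
    dC <- nd$grad
    dW <- matrix(0, B, L)
    for (l in seq_len(L)) {
      k <- nd$parents[[l + 1L]]
      acc_grad(k, dC * W[, l])
      dW[, l] <- rowSums(dC * k$value)
    }
    dS <- W * (dW - rowSums(dW * W))
    dq <- matrix(0, B, D)
    for (l in seq_len(L)) {
      k <- nd$parents[[l + 1L]]
      dq <- dq + dS[, l] * k$value
      acc_grad(k, dS[, l] * q$value * scale)
    }
    acc_grad(q, dq * scale)
  })
}

# Geometry for a 'same'-padded kh x kw convolution on an H x W image with
# cin channels. Feature maps are stored B x (H*W*c): column (c-1)*H*W + p,
# position p = (w-1)*H + h (column-major). `gmat[j, p]` is the padded-input
# column feeding patch entry j (j = (q-1)*cin + ci) of position p; `taps`
# holds, per kernel tap, the column-space scatter map used by the backward
# pass (within one tap every input column is touched at most once, so the
# scatter is kh*kw vectorized adds). Patch-gather index matrices depend on
# the batch size and are cached in `cache`.
conv_geom <- function(H, W, cin, cout, kh = 3L, kw = 3L) {
  npos <- H * W
  inner <- kh * kw * cin
  zero_col <- npos * cin + 1L
  ch <- (kh + 1L) %/% 2L
  cw <- (kw + 1L) %/% 2L
  pos_h <- rep(seq_len(H), times = W)
  pos_w <- rep(seq_len(W), each = H)

  gmat <- matrix(0L, inner, npos)
  taps <- vector("list", kh * kw)
  for (qw in seq_len(kw)) for (qh in seq_len(kh)) {
    q <- (qw - 1L) * kh + qh
    sh <- pos_h + qh - ch
    sw <- pos_w + qw - cw
    valid <- sh >= 1L & sh <= H & sw >= 1L & sw <= W
    s <- (sw - 1L) * H + sh
    for (ci in seq_len(cin)) {
      gmat[(q - 1L) * cin + ci, ] <- ifelse(valid, (ci - 1L) * npos + s, zero_col)
    }
    vp <- which(valid)
    # dPm reshaped to B x (inner*npos) has column (j-1)*npos + p
    taps[[q]] <- list(
      src = as.vector(outer(vp, ((q - 1L) * cin + seq_len(cin) - 1L) * npos, "+")),
      tgt = as.vector(outer(s[vp], (seq_len(cin) - 1L) * npos, "+"))
    )
  }
  list(H = H, W = W, cin = cin, cout = cout, kh = kh, kw = kw,
       npos = npos, inner = inner, zero_col = zero_col,
       gmat = gmat, taps = taps, cache = new.env(parent = emptyenv()),
       n_in = npos * cin, n_out = npos * cout)
}

# (B*npos) x inner matrix of vector indices into the padded input (viewed
# as a B x (n_in + 1) matrix), row (p-1)*B + b.
conv_gather_idx <- function(geom, B) {
  key <- as.character(B)
  idx <- geom$cache[[key]]
  if (is.null(idx)) {
    M <- t(geom$gmat)[rep(seq_len(geom$npos), each = B), , drop = FALSE]
    idx <- (M - 1L) * B + rep(seq_len(B), times = geom$npos)
    geom$cache[[key]] <- idx
  }
  idx
}

# 2-D convolution as an im2col matrix product. x: B x (npos*cin); K:
# inner x cout; b: length cout. Output B x (npos*cout).
nd_conv2d <- function(tape, x, K, b, geom) {
  B <- nrow(x$value)
  idx <- conv_gather_idx(geom, B)
  Xp <- cbind(x$value, 0)
  Pm <- Xp[idx]                                        # (B*npos) x inner
  dim(Pm) <- dim(idx)
  Y <- Pm %*% K$value + rep(b$value, each = B * geom$npos)
  out <- Y
  dim(out) <- c(B, geom$n_out)                         # col (co-1)*npos + p

  push_node(tape, out, list(x, K, b), function(nd) {
    x <- nd$parents[[1]]; K <- nd$parents[[2]]; b <- nd$parents[[3]]
    dY <- nd$grad
    dim(dY) <- c(B * geom$npos, geom$cout)
    acc_grad(K, crossprod(Pm, dY))
    acc_grad(b, colSums(dY))
    dPm <- tcrossprod(dY, K$value)                     # (B*npos) x inner
    dim(dPm) <- c(B, geom$npos * geom$inner)           # col (j-1)*npos + p
    dX <- matrix(0, B, geom$n_in)
    for (tap in geom$taps) {
      dX[, tap$tgt] <- dX[, tap$tgt] + dPm[, tap$src, drop = FALSE]
    }
    acc_grad(x, dX)
  })
}

# Fused position-tied site head. For each fragment length k the two decoder
# states flanking its cleavage (rows Lmax-k and Lmax-k+1), the attention
# context and the feature vector pass through a shared relu layer (W1, b1),
# then a per-k linear output (Wk, bk) emits the three charge slots of that
# k. The shared layer is evaluated as one stacked matrix product over all k.
# states: list of Lmax nodes (B x H); ctx, feat: nodes; Wks/bks: lists of
# 14 parameter nodes. Output: B x 42, column (k-1)*3 + z.
nd_site_head <- function(tape, states, ctx, feat, W1, b1, Wks, bks, Lmax) {
  K <- length(Wks)
  B <- nrow(ctx$value)
  Hs <- ncol(states[[1]]$value)
  extra <- cbind(ctx$value, feat$value)
  Hstack <- do.call(rbind, lapply(seq_len(K), function(k) {
    r <- Lmax - k
    cbind(states[[r]]$value, states[[r + 1L]]$value, extra)
  }))
  Z <- Hstack %*% W1$value + rep(b1$value, each = B * K)
  Zr <- pmax(Z, 0)
  out <- matrix(0, B, 3L * K)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * B + seq_len(B)
    out[, (k - 1L) * 3L + 1:3] <-
      Zr[rows, , drop = FALSE] %*% Wks[[k]]$value +
      rep(bks[[k]]$value, each = B)
  }

  push_node(tape, out, c(states, list(ctx, feat, W1, b1), Wks, bks),
            function(nd) {
    dZr <- matrix(0, B * K, ncol(W1$value))
    for (k in seq_len(K)) {
      rows <- (k - 1L) * B + seq_len(B)
      dok <- nd$grad[, (k - 1L) * 3L + 1:3, drop = FALSE]
      acc_grad(Wks[[k]], crossprod(Zr[rows, , drop = FALSE], dok))
      acc_grad(bks[[k]], colSums(dok))
      dZr[rows, ] <- tcrossprod(dok, Wks[[k]]$value)
    }
    dZ <- dZr * (Z > 0)
    acc_grad(W1, crossprod(Hstack, dZ))
    acc_grad(b1, colSums(dZ))
    dH <- tcrossprod(dZ, W1$value)
    dextra <- matrix(0, B, ncol(extra))
    for (k in seq_len(K)) {
      rows <- (k - 1L) * B + seq_len(B)
      r <- Lmax - k
      acc_grad(states[[r]], dH[rows, seq_len(Hs), drop = FALSE])
      acc_grad(states[[r + 1L]], dH[rows, Hs + seq_len(Hs), drop = FALSE])
      dextra <- dextra + dH[rows, 2L * Hs + seq_len(ncol(extra)), drop = FALSE]
    }
    acc_grad(ctx, dextra[, seq_len(ncol(ctx$value)), drop = FALSE])
    acc_grad(feat, dextra[, ncol(ctx$value) + seq_len(ncol(feat$value)),
                          drop = FALSE])
  })
}

# Weighted mean squared error: sum(w * (pred - target)^2) / sum(w).
# target and w are plain matrices (constants).
nd_wmse <- function(tape, pred, target, w) {
  diff <- pred$value - target
  denom <- sum(w)
  push_node(tape, sum(w * diff^2) / denom, list(pred), function(nd) {
    acc_grad(nd$parents[[1]], nd$grad * 2 * w * diff / denom)
  })
}
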