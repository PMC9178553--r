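# Every fused layer gradient is validated against central finite
# differences on random inputs (kept away from relu/max kinks by using
# smooth heads or random nonzero parameters).

fd_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (j in seq_along(x)) {
    x1 <- x; x1[j] <- x[j] + eps
    x0 <- x; x0[j] <- x[j] - eps
    g[j] <- (f(x1) - f(x0)) / (2 * eps)
  }
  g
}

test_that("elementwise and linear ops back-propagate correctly", {
  withr::with_seed(31L, {
    A <- matrix(rnorm(12), 3); B <- matrix(rnorm(12), 3)
    W <- matrix(rnorm(8), 4); bias <- rnorm(2)
    X <- matrix(rnorm(12), 3)
    Wt <- matrix(rnorm(12), 3)  # random linear functional as loss

    run <- function(Av) {
      tp <- tape_new()
      a <- nd_param(tp, Av); b <- nd_const(tp, B)
      z <- nd_mul(tp, nd_tanh(tp, a), nd_sigmoid(tp, nd_add(tp, a, b)))
      sum(Wt * z$value)
    }
    tp <- tape_new()
    a <- nd_param(tp, A); b <- nd_const(tp, B)
    z <- nd_mul(tp, nd_tanh(tp, a), nd_sigmoid(tp, nd_add(tp, a, b)))
    z$grad <- Wt
    backward(tp, z)   # seeds z with its preset grad; terminal grad 1 unused
    expect_equal(a$grad, fd_grad(run, A), tolerance = 1e-6)

    run_lin <- function(Xv) {
      tp <- tape_new()
      y <- nd_linear(tp, nd_param(tp, Xv), nd_param(tp, matrix(W, 4)),
                     nd_param(tp, bias))
      sum(tanh(y$value))
    }
    tp <- tape_new()
    xn <- nd_param(tp, X); wn <- nd_param(tp, matrix(W, 4)); bn <- nd_param(tp, bias)
    y <- nd_linear(tp, xn, wn, bn)
    loss <- push_node(tp, sum(tanh(y$value)), list(y), function(nd)
      acc_grad(nd$parents[[1]], nd$grad * (1 - tanh(y$value)^2)))
    backward(tp, loss)
    expect_equal(xn$grad, fd_grad(run_lin, X), tolerance = 1e-6)
    expect_equal(bn$grad,
                 fd_grad(function(bv) {
                   tp <- tape_new()
                   y <- nd_linear(tp, nd_const(tp, X), nd_const(tp, matrix(W, 4)),
                                  nd_param(tp, bv))
                   sum(tanh(y$value))
                 }, bias), tolerance = 1e-6)
  })
})

test_that("the fused GRU step matches finite differences", {
  withr::with_seed(32L, {
    B <- 3L; D <- 5L; H <- 4L
    x <- matrix(rnorm(B * D), B); h <- matrix(rnorm(B * H), B)
    Wx <- matrix(rnorm(D * 3 * H, sd = 0.4), D)
    Wh <- matrix(rnorm(H * 3 * H, sd = 0.4), H)
    bx <- rnorm(3 * H, sd = 0.2); bh <- rnorm(3 * H, sd = 0.2)
    mask <- c(1, 0, 1)
    Wt <- matrix(rnorm(B * H), B)

    eval_loss <- function(xv, hv, Wxv, Whv, bxv, bhv) {
      tp <- tape_new()
      out <- nd_gru_step(tp, nd_const(tp, xv), nd_const(tp, hv),
                         nd_const(tp, Wxv), nd_const(tp, Whv),
                         nd_const(tp, bxv), nd_const(tp, bhv), mask = mask)
      sum(Wt * out$value)
    }
    tp <- tape_new()
    nds <- list(x = nd_param(tp, x), h = nd_param(tp, h),
                Wx = nd_param(tp, Wx), Wh = nd_param(tp, Wh),
                bx = nd_param(tp, bx), bh = nd_param(tp, bh))
    out <- nd_gru_step(tp, nds$x, nds$h, nds$Wx, nds$Wh, nds$bx, nds$bh,
                       mask = mask)
    out$grad <- Wt
    backward(tp, out)
    expect_equal(nds$x$grad,
                 fd_grad(function(v) eval_loss(v, h, Wx, Wh, bx, bh), x),
                 tolerance = 1e-6)
    expect_equal(nds$h$grad,
                 fd_grad(function(v) eval_loss(x, v, Wx, Wh, bx, bh), h),
                 tolerance = 1e-6)
    expect_equal(nds$Wx$grad,
                 fd_grad(function(v) eval_loss(x, h, v, Wh, bx, bh), Wx),
                 tolerance = 1e-6)
    expect_equal(nds$Wh$grad,
                 fd_grad(function(v) eval_loss(x, h, Wx, v, bx, bh), Wh),
                 tolerance = 1e-6)
    expect_equal(nds$bx$grad,
                 fd_grad(function(v) eval_loss(x, h, Wx, Wh, v, bh), bx),
                 tolerance = 1e-6)
    expect_equal(nds$bh$grad,
                 fd_grad(function(v) eval_loss(x, h, Wx, Wh, bx, v), bh),
                 tolerance = 1e-6)
    # masked rows keep their previous state
    expect_equal(out$value[2, ], h[2, ])
  })
})

test_that("fused attention matches finite differences and normalizes", {
  withr::with_seed(33L, {
    B <- 3L; D <- 4L; L <- 5L
    q <- matrix(rnorm(B * D), B)
    K <- lapply(1:L, function(l) matrix(rnorm(B * D), B))
    km <- matrix(TRUE, B, L); km[2, 4:5] <- FALSE
    Wt <- matrix(rnorm(B * D), B)

    eval_loss <- function(qv, Kv) {
      tp <- tape_new()
      out <- nd_attention(tp, nd_const(tp, qv),
                          lapply(Kv, function(k) nd_const(tp, k)), km)
      sum(Wt * out$value)
    }
    tp <- tape_new()
    qn <- nd_param(tp, q)
    Kn <- lapply(K, function(k) nd_param(tp, k))
    out <- nd_attention(tp, qn, Kn, km)
    out$grad <- Wt
    backward(tp, out)
    expect_equal(qn$grad, fd_grad(function(v) eval_loss(v, K), q),
                 tolerance = 1e-6)
    for (l in c(1L, 4L)) {
      expect_equal(Kn[[l]]$grad,
                   fd_grad(function(v) {
                     K2 <- K; K2[[l]] <- v; eval_loss(q, K2)
                   }, K[[l]]), tolerance = 1e-6)
    }
  })
})

test_that("fused convolution matches finite differences", {
  withr::with_seed(34L, {
    geom <- conv_geom(4L, 12L, 2L, 3L)
    B <- 2L
    X <- matrix(rnorm(B * geom$n_in), B)
    K <- matrix(rnorm(geom$inner * geom$cout, sd = 0.3), geom$inner)
    bias <- rnorm(geom$cout, sd = 0.2)
    Wt <- matrix(rnorm(B * geom$n_out), B)

    eval_loss <- function(Xv, Kv, bv) {
      tp <- tape_new()
      out <- nd_conv2d(tp, nd_const(tp, Xv), nd_const(tp, Kv),
                       nd_const(tp, bv), geom)
      sum(Wt * out$value)
    }
    tp <- tape_new()
    xn <- nd_param(tp, X); kn <- nd_param(tp, K); bn <- nd_param(tp, bias)
    out <- nd_conv2d(tp, xn, kn, bn, geom)
    out$grad <- Wt
    backward(tp, out)
    expect_equal(xn$grad, fd_grad(function(v) eval_loss(v, K, bias), X),
                 tolerance = 1e-5)
    expect_equal(kn$grad, fd_grad(function(v) eval_loss(X, v, bias), K),
                 tolerance = 1e-5)
    expect_equal(bn$grad, fd_grad(function(v) eval_loss(X, K, v), bias),
                 tolerance = 1e-5)
  })
})

test_that("weighted MSE node value and gradient are exact", {
  withr::with_seed(35L, {
    P <- matrix(rnorm(12), 3); T0 <- matrix(rnorm(12), 3)
    W <- matrix(rexp(12), 3)
    tp <- tape_new()
    pn <- nd_param(tp, P)
    loss <- nd_wmse(tp, pn, T0, W)
    expect_equal(loss$value, sum(W * (P - T0)^2) / sum(W))
    backward(tp, loss)
    expect_equal(pn$grad,
                 fd_grad(function(v) sum(W * (v - T0)^2) / sum(W), P),
                 tolerance = 1e-6)
  })
})

test_that("full-model gradients agree with finite differences", {
  ds <- small_encoded(4L)
  m <- random_params_model(tiny_model_config())
  g <- model_graph(m, ds)
  w <- matrix(1, n_samples(ds), 42)
  loss <- nd_wmse(g$tape, g$out, ds$target, w)
  backward(g$tape, loss)
  withr::with_seed(36L, {
    for (nm in c("enc_f_Wx", "enc_b_Wh", "cnn_K2", "cnn_b3", "merge_Wg",
                 "dec_Wx", "head_W1", "head_Wk05", "dec0_W", "enc_f_bh")) {
      an <- g$pnodes[[nm]]$grad
      for (j in sample(length(m$params[[nm]]), 3L)) {
        eps <- 1e-5
        m2 <- m; m2$params[[nm]][j] <- m$params[[nm]][j] + eps
        l1 <- loss_mse(forward(m2, ds), ds$target)
        m2$params[[nm]][j] <- m$params[[nm]][j] - eps
        l0 <- loss_mse(forward(m2, ds), ds$target)
        expect_equal(an[j], (l1 - l0) / (2 * eps), tolerance = 1e-4,
                     label = sprintf("grad of %s[%d]", nm, j))
      }
    }
  })
})
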