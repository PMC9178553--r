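# Optimization: Adam with a reduce-on-plateau schedule, the training loop,
# k-fold splitting and cross-validated training.

#' Training configuration
#'
#' Defaults: Adam at learning rate 0.01 with a
#' reduce-on-plateau schedule (mode min, factor 0.1, patience 7) on the
#' validation loss. Maximum epochs and early stopping are this package's
#' choices (the recipe states neither); early stopping waits twice the
#' scheduler patience.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param factor Multiplicative LR reduction on plateau.
#' @param patience Consecutive non-improving epochs before an LR reduction.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Non-improving epochs before stopping (`Inf`
#'   disables early stopping).
#' @param folds Folds for [cross_validate()].
#' @param loss `"mse"` (default) or `"topk"` for the top-k weighted
#'   objective.
#' @param topk_weight,topk_k Parameters of the top-k objective.
#' @param mask_infeasible Exclude -1 slots from the training loss (default
#'   `FALSE`: the loss runs over all 42 slots).
#' @param seed Seed controlling shuffling, dropout and fold assignment.
#' @return A `TrainConfig` list.
#' @export
train_config <- function(learning_rate = 0.01, factor = 0.1, patience = 7L,
                         batch_size = 256L, max_epochs = 100L,
                         early_stop_patience = 15L, folds = 10L,
                         loss = c("mse", "topk"), topk_weight = 0.5,
                         topk_k = 3L, mask_infeasible = FALSE, seed = 1L) {
  stopifnot(learning_rate > 0, folds >= 2L)
  structure(list(learning_rate = learning_rate, factor = factor,
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 folds = as.integer(folds), loss = match.arg(loss),
                 topk_weight = topk_weight, topk_k = as.integer(topk_k),
                 mask_infeasible = mask_infeasible, seed = as.integer(seed)),
            class = "yfrag_train_config")
}

#' Desk-scale training configuration
#'
#' Companion of [desk_model_config()]: the standard optimizer recipe (Adam
#' at 0.01, plateau schedule) run for 30 epochs at batch size 128.
#'
#' @param seed Shuffling/fold seed.
#' @param ... Overrides passed to [train_config()].
#' @return A [train_config()].
#' @export
desk_train_config <- function(seed = 1L, ...) {
  do.call(train_config, utils::modifyList(
    list(max_epochs = 30L, batch_size = 128L, seed = seed),
    list(...)))
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Returns a stateful stepper: `step(loss)` records one epoch's monitored
#' loss and returns the learning rate to use next. The rate is multiplied by
#' `factor` once `patience` consecutive epochs fail to improve on the best
#' loss seen by at least the relative `threshold`.
#'
#' @param lr Initial learning rate.
#' @param factor Reduction factor.
#' @param patience Non-improving epochs tolerated before a reduction.
#' @param threshold Relative improvement below which an epoch counts as
#'   non-improving.
#' @param min_lr Floor for the learning rate.
#' @return A list with functions `step(loss)` and `state()`.
#' @export
plateau_scheduler <- function(lr, factor = 0.1, patience = 7L,
                              threshold = 1e-4, min_lr = 1e-7) {
  best <- Inf; bad <- 0L
  list(
    step = function(loss) {
      if (is.finite(loss) && loss < best * (1 - threshold)) {
        best <<- loss; bad <<- 0L
      } else {
        bad <<- bad + 1L
        if (bad >= patience) {
          lr <<- max(lr * factor, min_lr)
          bad <<- 0L
        }
      }
      lr
    },
    state = function() list(lr = lr, best = best, bad = bad)
  )
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

train_loss_weights <- function(ds, config) {
  if (config$mask_infeasible) ds$mask * 1 else
    matrix(1, nrow(ds$target), ncol(ds$target))
}

batch_loss_node <- function(tp, out, ds, config) {
  w <- train_loss_weights(ds, config)
  base <- nd_wmse(tp, out, ds$target, w)
  if (config$loss == "topk") {
    wk <- topk_weight_matrix(ds$target, ds$mask, config$topk_k)
    nd_axpy(tp, base, nd_wmse(tp, out, ds$target, wk),
            1, config$topk_weight)
  } else {
    base
  }
}

eval_loss <- function(pred, ds, config) {
  if (config$loss == "topk") {
    loss_topk_weighted(pred, ds$target,
                       mask = if (config$mask_infeasible) ds$mask,
                       k = config$topk_k, weight = config$topk_weight)
  } else {
    loss_mse(pred, ds$target, mask = ds$mask,
             mask_infeasible = config$mask_infeasible)
  }
}

#' Predict intensities for an encoded dataset
#'
#' Evaluation-mode forward pass in memory-bounded batches.
#'
#' @param model A `yfrag_model`.
#' @param ds A `yfrag_dataset`.
#' @param batch_size Rows per forward pass.
#' @return A `N x 42` prediction matrix.
#' @export
predict_matrix <- function(model, ds, batch_size = 512L) {
  n <- n_samples(ds)
  out <- matrix(NA_real_, n, N_SLOTS)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- forward(model, dataset_subset(ds, idx))
  }
  out
}

#' Train a model
#'
#' Minibatch Adam with the plateau schedule on the validation loss. The
#' checkpoint with the lowest validation loss is retained and returned.
#'
#' @param model A `yfrag_model` (freshly built or partially trained).
#' @param train_ds,valid_ds Encoded datasets with targets.
#' @param config A [train_config()].
#' @param quiet Suppress per-epoch progress on stderr.
#' @return A `yfrag_fit`: list with the best `model`, a `history` tibble
#'   (`epoch`, `train_loss`, `valid_loss`, `lr`), `best_epoch` and the
#'   configs.
#' @export
train_model <- function(model, train_ds, valid_ds, config = train_config(),
                        quiet = TRUE) {
  n <- n_samples(train_ds)
  sched <- plateau_scheduler(config$learning_rate, config$factor, config$patience)
  opt <- adam_new(model$params)
  lr <- config$learning_rate
  history <- vector("list", config$max_epochs)
  best_valid <- Inf; best_params <- model$params; best_epoch <- 0L; bad <- 0L

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1L, n, by = config$batch_size)
      tl_sum <- 0
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
        bds <- dataset_subset(train_ds, idx)
        g <- model_graph(model, bds, training = TRUE)
        loss_nd <- batch_loss_node(g$tape, g$out, bds, config)
        if (!is.finite(loss_nd$value)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
               call. = FALSE)
        }
        backward(g$tape, loss_nd)
        grads <- lapply(g$pnodes, `[[`, "grad")
        upd <- adam_step(opt, model$params, grads, lr)
        opt <- upd$state
        model$params <- upd$params
        tl_sum <- tl_sum + loss_nd$value * length(idx)
      }
      train_loss <- tl_sum / n
      valid_pred <- predict_matrix(model, valid_ds)
      valid_loss <- eval_loss(valid_pred, valid_ds, config)
      if (!is.finite(valid_loss)) {
        stop(sprintf("training diverged (non-finite validation loss) at epoch %d",
                     epoch), call. = FALSE)
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                         valid_loss = valid_loss, lr = lr)
      if (!quiet) {
        message(sprintf("epoch %3d  train %.5f  valid %.5f  lr %.2g",
                        epoch, train_loss, valid_loss, lr))
      }
      if (valid_loss < best_valid - 1e-12) {
        best_valid <- valid_loss; best_params <- model$params
        best_epoch <- epoch; bad <- 0L
      } else {
        bad <- bad + 1L
      }
      lr <- sched$step(valid_loss)
      if (bad >= config$early_stop_patience) break
    }
  })
  model$params <- best_params
  structure(list(model = model,
                 history = dplyr::bind_rows(history),
                 best_epoch = best_epoch, best_valid_loss = best_valid,
                 train_config = config, n_train = n),
            class = "yfrag_fit")
}

#' @export
print.yfrag_fit <- function(x, ...) {
  cat(sprintf("# Trained intensity model: %d epochs, best valid loss %.5f (epoch %d)\n",
              nrow(x$history), x$best_valid_loss, x$best_epoch))
  invisible(x)
}

#' k-fold split
#'
#' Shuffled, near-equal partition: validation sets are disjoint, jointly
#' exhaustive, and their sizes differ by at most one. Deterministic given
#' the seed.
#'
#' @param n Number of samples (or a `yfrag_dataset`).
#' @param folds Number of folds (default 10).
#' @param seed Shuffle seed.
#' @return A list of `folds` elements, each `list(train, valid)` of index
#'   vectors.
#' @export
kfold_split <- function(n, folds = 10L, seed = 1L) {
  if (inherits(n, "yfrag_dataset")) n <- n_samples(n)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  ord <- withr::with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(folds), length.out = n)
  lapply(seq_len(folds), function(f) {
    valid <- sort(ord[fold_of == f])
    list(train = setdiff(seq_len(n), valid), valid = valid)
  })
}

#' Cross-validated training
#'
#' Trains one model per fold (9/10 train, 1/10 validation with the default
#' 10 folds) and scores each fold's retained checkpoint on a common
#' evaluation set by the median without-zero Pearson correlation.
#'
#' @param ds Encoded training corpus.
#' @param eval_ds Encoded held-out evaluation set.
#' @param mconfig A [model_config()]; each fold is built with seed
#'   `mconfig$seed + fold`.
#' @param tconfig A [train_config()].
#' @param quiet Suppress progress.
#' @return A `yfrag_cv`: list with `fits` (per-fold `yfrag_fit`),
#'   `fold_pcc` tibble, `mean_median_pcc`, `sd_median_pcc`, `best_fold`.
#' @export
cross_validate <- function(ds, eval_ds, mconfig = model_config(),
                           tconfig = train_config(), quiet = TRUE) {
  splits <- kfold_split(n_samples(ds), tconfig$folds, tconfig$seed)
  fits <- vector("list", length(splits))
  medians <- numeric(length(splits))
  for (f in seq_along(splits)) {
    mcf <- mconfig; mcf$seed <- mconfig$seed + f
    fold_model <- build_model(mcf)
    tcf <- tconfig; tcf$seed <- tconfig$seed + f
    fit <- train_model(fold_model, dataset_subset(ds, splits[[f]]$train),
                       dataset_subset(ds, splits[[f]]$valid), tcf, quiet = quiet)
    pred <- predict_matrix(fit$model, eval_ds)
    pcc <- pcc_per_peptide(pred, eval_ds)
    medians[f] <- stats::median(pcc$pcc_without_zero, na.rm = TRUE)
    fits[[f]] <- fit
    if (!quiet) message(sprintf("fold %d: median without-zero PCC %.4f",
                                f, medians[f]))
  }
  structure(list(fits = fits,
                 fold_pcc = tibble::tibble(fold = seq_along(splits),
                                           median_pcc = medians),
                 mean_median_pcc = mean(medians),
                 sd_median_pcc = stats::sd(medians),
                 best_fold = which.max(medians)),
            class = "yfrag_cv")
}

#' @export
print.yfrag_cv <- function(x, ...) {
  cat(sprintf("# %d-fold cross-validation: median PCC %.4f +/- %.4f (best fold %d)\n",
              nrow(x$fold_pcc), x$mean_median_pcc, x$sd_median_pcc, x$best_fold))
  invisible(x)
}
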