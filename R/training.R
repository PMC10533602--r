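#' Masked logarithmic loss configuration
#'
#' The training loss penalises the logarithm of the absolute
#' reconstruction error, `log((|y - yhat| + epsilon) / k)`, summed over the
#' lines the probe did not acquire. The log shape concentrates the
#' optimisation pressure on pixels that are already close to the target
#' (errors below `k` contribute negatively), which sharpens visual
#' similarity; `epsilon` keeps the logarithm finite at zero error; `k` sets
#' where the loss crosses zero -- 5 grey levels, i.e. `5/255` on normalised
#' data.
#'
#' Acquired lines are copied bit-exactly by the cubic up-sampler, so
#' penalising them would be vacuous: the default `mask_convention =
#' "interpolated"` sums over all lines with `(l - phase) mod s != 0`
#' (0-based `l`). The alternative `"equation"` reproduces the literal
#' residue-class form `mod(l, s) == 0` with 1-based line indices, which
#' covers one interpolated line per group of `s`.
#'
#' @param s Acquisition stride; equals the up-sampling factor (2 or 4).
#' @param epsilon Positive offset inside the logarithm (default `1e-4`,
#'   well below `1/255`, the smallest nonzero normalised pixel difference).
#' @param k Curvature constant (default `5/255`); must exceed `epsilon`.
#' @param mask_convention `"interpolated"` (default) or `"equation"`; see
#'   above.
#' @param phase 0-based index of the first acquired line.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(s, epsilon = 1e-4, k = 5 / 255,
                        mask_convention = c("interpolated", "equation"),
                        phase = 0L) {
  s <- as.integer(s)
  if (!s %in% c(2L, 4L)) stop("`s` must be 2 or 4")
  if (epsilon <= 0) stop("`epsilon` must be positive")
  if (k <= epsilon) stop("`k` must exceed `epsilon`")
  structure(list(s = s, epsilon = epsilon, k = k,
                 mask_convention = match.arg(mask_convention),
                 phase = as.integer(phase)),
            class = "loss_config")
}

# Logical vector over 0-based line indices: TRUE where the line
# contributes to the loss.
loss_line_mask <- function(n_lines, cfg) {
  l <- seq_len(n_lines) - 1L
  switch(cfg$mask_convention,
    interpolated = (l - cfg$phase) %% cfg$s != 0L,
    equation = (l + 1L) %% cfg$s == 0L
  )
}

#' Masked logarithmic loss
#'
#' Reference (pure R) implementation of the training loss: the sum of
#' `log((|y - yhat| + epsilon) / k)` over all depth samples of the masked
#' lines (natural logarithm). At zero error the loss attains its global
#' minimum `N_masked * log(epsilon / k)`; pixels on acquired lines
#' contribute exactly zero and have identically zero gradient.
#'
#' @param y Target image (`us_image` in unit range, or matrix in `[0, 1]`).
#' @param yhat Prediction, same shape.
#' @param cfg A [loss_config()].
#' @param gradient If `TRUE`, also return the gradient of the loss with
#'   respect to `yhat`.
#' @return The loss value, or (with `gradient = TRUE`) a list with `loss`
#'   and `grad` (matrix shaped like `yhat`).
#' @export
masked_log_loss <- function(y, yhat, cfg, gradient = FALSE) {
  stopifnot(inherits(cfg, "loss_config"))
  Y <- pixel_matrix(y); Yh <- pixel_matrix(yhat)
  check_same_dim(Y, Yh)
  mask <- loss_line_mask(nrow(Y), cfg)
  e <- Yh[mask, , drop = FALSE] - Y[mask, , drop = FALSE]
  ae <- abs(e) + cfg$epsilon
  loss <- sum(log(ae / cfg$k))
  if (!gradient) return(loss)
  g <- matrix(0, nrow(Y), ncol(Y))
  g[mask, ] <- sign(e) / ae
  list(loss = loss, grad = g)
}

#' Training configuration
#'
#' Fixed-epoch Adam training with a geometrically decaying learning rate.
#' The rate decays from `lr_init` by a constant per-epoch factor and is
#' clipped below at `lr_floor` (`1e-6`); by default the decay factor is
#' chosen so the floor is reached exactly at the final epoch, mirroring an
#' "iteratively decreasing, down to 1e-6" schedule at any epoch budget.
#' There is no early stopping.
#'
#' @param epochs Number of epochs (the reference regime is 200; scaled-down
#'   experiments default to 30).
#' @param batch_size Mini-batch size.
#' @param lr_init Initial learning rate.
#' @param lr_floor Learning-rate floor.
#' @param lr_decay Per-epoch multiplicative decay; `NULL` (default) derives
#'   it from `epochs` so that `lr_init * decay^(epochs-1) = lr_floor`.
#' @param seed Integer seed controlling initialisation and batch shuffling.
#' @param shuffle Reshuffle the training pairs each epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 16L, lr_init = 1e-3,
                         lr_floor = 1e-6, lr_decay = NULL, seed = 1L,
                         shuffle = TRUE) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (lr_floor > lr_init) stop("`lr_floor` must not exceed `lr_init`")
  if (is.null(lr_decay)) {
    lr_decay <- if (epochs > 1L) (lr_floor / lr_init)^(1 / (epochs - 1L)) else 1
  }
  if (lr_decay <= 0 || lr_decay > 1) stop("`lr_decay` must be in (0, 1]")
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_floor = lr_floor, lr_decay = lr_decay,
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @param cfg A [train_config()].
#' @return The learning rate: `max(lr_init * lr_decay^epoch, lr_floor)`,
#'   a non-increasing sequence starting at `lr_init`.
#' @export
lr_at_epoch <- function(epoch, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (any(epoch < 0 | epoch >= cfg$epochs)) {
    stop("`epoch` must satisfy 0 <= epoch < epochs")
  }
  pmax(cfg$lr_init * cfg$lr_decay^epoch, cfg$lr_floor)
}

# Backpropagate an effective-weight gradient through the weight-norm
# reparameterisation w = g * v / |v| (per output channel).
weight_norm_backward <- function(cv, gW) {
  if (is.null(cv$g)) return(list(gV = gW, gg = NULL))
  nrm <- sqrt(colSums(cv$V^2))
  nrm[nrm == 0] <- Inf                 # zero-direction channels stay frozen
  dots <- colSums(gW * cv$V)
  gg <- dots / nrm
  gV <- sweep(gW, 2L, cv$g / nrm, `*`) -
    sweep(cv$V, 2L, cv$g * dots / nrm^3, `*`)
  list(gV = gV, gg = gg)
}

adam_init <- function(x) list(m = x * 0, v = x * 0)

adam_update <- function(x, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the custom-WDSR network
#'
#' Optimises the masked logarithmic loss over (cubic-up-sampled, target)
#' pairs with Adam and the decaying learning-rate schedule of
#' [train_config()]. The loss is summed per image as defined and averaged
#' over the mini-batch, so learning rates are batch-size independent.
#' Training is fully reproducible for a fixed seed.
#'
#' @param model A `wdsr_model` from [build_network()].
#' @param pairs Nonempty list of `list(input =, target =)` pairs (from
#'   [make_training_pair()]); all images must share one shape and be on
#'   the `[0, 1]` scale.
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [loss_config()]; its stride must equal the model's
#'   up-sampling factor.
#' @param validation Optional list of pairs monitored (never trained on)
#'   via the median validation PSNR after each epoch.
#' @param verbose Print one line per epoch.
#' @return A list with the trained `model` and `history`, a data frame
#'   with one row per epoch: `epoch`, `lr`, `train_loss` (mean per-image
#'   masked loss) and `val_psnr` (median, `NA` without validation data).
#' @export
train_network <- function(model, pairs, train_cfg, loss_cfg,
                          validation = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "wdsr_model"), inherits(train_cfg, "train_config"),
            inherits(loss_cfg, "loss_config"))
  if (length(pairs) == 0) stop("empty training set")
  if (loss_cfg$s != model$cfg$up_factor) {
    stop("loss stride `s` must equal the model's up-sampling factor")
  }
  xs <- lapply(pairs, function(p) pixel_matrix(p$input))
  ys <- lapply(pairs, function(p) pixel_matrix(p$target))
  dims <- vapply(xs, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all training pairs must share one shape")
  L <- dims[1, 1]; D <- dims[2, 1]
  mask <- matrix(0, L, D)
  mask[loss_line_mask(L, loss_cfg), ] <- 1
  mask_vec <- as.vector(mask)
  ys <- lapply(ys, as.vector)

  convs <- model$convs
  opt <- lapply(convs, function(cv) {
    list(V = adam_init(cv$V),
         g = if (!is.null(cv$g)) adam_init(cv$g),
         b = adam_init(cv$b))
  })
  n <- length(pairs)
  history <- data.frame(epoch = seq_len(train_cfg$epochs), lr = NA_real_,
                        train_loss = NA_real_, val_psnr = NA_real_)
  set.seed(train_cfg$seed)
  t_step <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    lr <- lr_at_epoch(epoch - 1L, train_cfg)
    ord <- if (train_cfg$shuffle) sample.int(n) else seq_len(n)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    epoch_losses <- numeric(0)
    for (batch in batches) {
      model$convs <- convs
      eff <- effective_weights(model)
      acc_gW <- NULL; acc_gb <- NULL
      batch_loss <- 0
      for (i in batch) {
        res <- wdsr_pass(as.vector(xs[[i]]) - model$mean_shift, L, D,
                         eff$W, eff$b, eff$k, model$cfg$n_blocks,
                         model$mean_shift, ys[[i]], mask_vec,
                         loss_cfg$epsilon, loss_cfg$k, TRUE)
        if (!is.finite(res$loss)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        }
        batch_loss <- batch_loss + res$loss
        if (is.null(acc_gW)) {
          acc_gW <- res$gW; acc_gb <- res$gb
        } else {
          acc_gW <- Map(`+`, acc_gW, res$gW)
          acc_gb <- Map(`+`, acc_gb, res$gb)
        }
      }
      nb <- length(batch)
      epoch_losses <- c(epoch_losses, batch_loss / nb)
      t_step <- t_step + 1L
      for (ci in seq_along(convs)) {
        cv <- convs[[ci]]
        wb <- weight_norm_backward(cv, acc_gW[[ci]] / nb)
        up <- adam_update(cv$V, wb$gV, opt[[ci]]$V, lr, t_step)
        cv$V <- up$x; opt[[ci]]$V <- up$state
        if (!is.null(cv$g)) {
          up <- adam_update(cv$g, wb$gg, opt[[ci]]$g, lr, t_step)
          cv$g <- up$x; opt[[ci]]$g <- up$state
        }
        up <- adam_update(cv$b, acc_gb[[ci]] / nb, opt[[ci]]$b, lr, t_step)
        cv$b <- up$x; opt[[ci]]$b <- up$state
        convs[[ci]] <- cv
      }
    }
    model$convs <- convs
    history$lr[epoch] <- lr
    history$train_loss[epoch] <- mean(epoch_losses)
    if (!is.null(validation) && length(validation) > 0) {
      vp <- vapply(validation, function(p) {
        us_psnr(p$target, predict(model, p$input))
      }, numeric(1))
      history$val_psnr[epoch] <- median(vp)
    }
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %10.2f  val PSNR %s",
                      epoch, lr, history$train_loss[epoch],
                      ifelse(is.na(history$val_psnr[epoch]), "-",
                             sprintf("%.2f", history$val_psnr[epoch]))))
    }
  }
  list(model = model, history = history)
}
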