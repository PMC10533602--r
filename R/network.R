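#' Configuration of the custom wide-activation residual network
#'
#' The refinement network is a WDSR-A-style fully convolutional model that
#' maps a cubic-up-sampled image to an approximation of the high-resolution
#' target at constant resolution (no pixel shuffling or deconvolution
#' anywhere, since line interpolation has already been done). Architecture:
#' fixed mean-shift normalisation, a head convolution (1 -> `n_feats`),
#' `n_blocks` residual blocks with wide activation (expand by `expansion`
#' before the ReLU, contract back, add the identity), a tail convolution
#' back to one channel, and a global `skip_kernel` x `skip_kernel`
#' convolution from the input added to the tail output before
#' denormalisation. All convolutions are weight-normalised (direction
#' tensor plus per-output-channel scale) when `weight_norm = TRUE`.
#'
#' The in-block kernel size follows the up-sampling factor: 3x3 for 2X and
#' 5x5 for 4X, so every kernel footprint spans at least two lines that were
#' physically acquired by the probe. The pinned widths are `n_feats = 32`
#' for 2X (888,989 trainable parameters, i.e. the 889K configuration) and
#' `n_feats = 10` for 4X.
#'
#' @param up_factor Up-sampling factor, 2 or 4; fixes `kernel_size`.
#' @param n_feats Feature-channel width; defaults to the pinned width for
#'   the chosen factor (32 for 2X, 10 for 4X).
#' @param expansion Width multiplier applied before each block's ReLU.
#' @param n_blocks Number of residual blocks.
#' @param weight_norm Use weight-normalised convolutions (adds one scale
#'   per output channel).
#' @param skip_kernel Kernel size of the global input -> output skip
#'   convolution.
#' @return An object of class `network_config`.
#' @export
network_config <- function(up_factor, n_feats = NULL, expansion = 6L,
                           n_blocks = 8L, weight_norm = TRUE,
                           skip_kernel = 5L) {
  up_factor <- as.integer(up_factor)
  if (!up_factor %in% c(2L, 4L)) stop("`up_factor` must be 2 or 4")
  kernel_size <- if (up_factor == 2L) 3L else 5L
  if (is.null(n_feats)) n_feats <- if (up_factor == 2L) 32L else 10L
  n_feats <- as.integer(n_feats); expansion <- as.integer(expansion)
  n_blocks <- as.integer(n_blocks); skip_kernel <- as.integer(skip_kernel)
  if (n_feats < 1L || expansion < 1L || n_blocks < 0L) {
    stop("`n_feats`, `expansion` must be >= 1 and `n_blocks` >= 0")
  }
  if (skip_kernel %% 2L != 1L) stop("`skip_kernel` must be odd")
  stopifnot(kernel_size >= up_factor)  # >= 2 acquired lines per footprint
  structure(list(up_factor = up_factor, kernel_size = kernel_size,
                 n_feats = n_feats, expansion = expansion,
                 n_blocks = n_blocks, weight_norm = as.logical(weight_norm),
                 skip_kernel = skip_kernel),
            class = "network_config")
}

# Parameters of one convolution: k*k*ci*co kernel weights, one scale per
# output channel when weight-normalised, and one bias per output channel.
conv_param_count <- function(k, ci, co, weight_norm) {
  k * k * ci * co + (if (weight_norm) co else 0L) + co
}

#' Closed-form trainable-parameter count
#'
#' Sums kernel weights, per-output-channel weight-norm scales and biases
#' over the head, all residual blocks, the tail and the global skip
#' convolution. Equals the count obtained by enumerating the tensors of an
#' instantiated model ([model_parameter_count()]) exactly. The pinned 2X
#' configuration yields 888,989 (the 889K network).
#'
#' @param cfg A [network_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  k <- cfg$kernel_size; nf <- cfg$n_feats; ex <- cfg$expansion
  wn <- cfg$weight_norm
  head <- conv_param_count(k, 1L, nf, wn)
  block <- conv_param_count(k, nf, nf * ex, wn) +
    conv_param_count(k, nf * ex, nf, wn)
  tail <- conv_param_count(k, nf, 1L, wn)
  skip <- conv_param_count(cfg$skip_kernel, 1L, 1L, wn)
  head + cfg$n_blocks * block + tail + skip
}

# He-uniform kernel initialisation, flattened to (k*k*ci) x co.
he_uniform <- function(k, ci, co) {
  bound <- sqrt(6 / (k * k * ci))
  matrix(runif(k * k * ci * co, -bound, bound), k * k * ci, co)
}

new_conv <- function(k, ci, co, weight_norm, V = NULL) {
  if (is.null(V)) V <- he_uniform(k, ci, co)
  list(V = V, g = if (weight_norm) rep(1, co) else NULL,
       b = rep(0, co), k = k, ci = ci, co = co)
}

#' Instantiate the custom-WDSR model
#'
#' Builds the parameter tensors for the architecture described in
#' [network_config()]. Kernels are He-uniform initialised from the current
#' R random stream (seed the stream for reproducibility). Two tensors are
#' initialised specially so that the untrained model starts exactly at the
#' identity on its cubic-interpolated input: the global skip convolution is
#' a delta kernel, and the tail scale (or tail kernel, without weight
#' normalisation) is zero, silencing the residual body until training
#' moves it. Training therefore refines the interpolation baseline rather
#' than rediscovering it.
#'
#' @param cfg A [network_config()].
#' @param mean_shift Fixed normalisation offset: the mean intensity of the
#'   training inputs, subtracted before the head and restored after the
#'   skip sum. Not trainable.
#' @return An object of class `wdsr_model`.
#' @export
build_network <- function(cfg, mean_shift = 0.5) {
  stopifnot(inherits(cfg, "network_config"))
  k <- cfg$kernel_size; nf <- cfg$n_feats; ex <- cfg$expansion
  wn <- cfg$weight_norm
  convs <- list(head = new_conv(k, 1L, nf, wn))
  for (i in seq_len(cfg$n_blocks)) {
    convs[[sprintf("block%02d_expand", i)]] <- new_conv(k, nf, nf * ex, wn)
    convs[[sprintf("block%02d_contract", i)]] <- new_conv(k, nf * ex, nf, wn)
  }
  tail_conv <- new_conv(k, nf, 1L, wn)
  if (wn) tail_conv$g <- 0 else tail_conv$V[] <- 0
  convs$tail <- tail_conv
  sk <- cfg$skip_kernel
  delta <- matrix(0, sk * sk, 1L)
  delta[(sk * sk + 1L) / 2L, 1L] <- 1
  convs$skip <- new_conv(sk, 1L, 1L, wn, V = delta)
  structure(list(cfg = cfg, mean_shift = mean_shift, convs = convs),
            class = "wdsr_model")
}

#' Count the parameters of an instantiated model
#'
#' Enumerates every trainable tensor (kernel directions, weight-norm
#' scales, biases) of a built model; the independent closed form
#' [count_parameters()] must agree with this exactly.
#'
#' @param model A `wdsr_model`.
#' @return Integer parameter count.
#' @export
model_parameter_count <- function(model) {
  stopifnot(inherits(model, "wdsr_model"))
  sum(vapply(model$convs, function(cv) {
    length(cv$V) + length(cv$g) + length(cv$b)
  }, integer(1)))
}

# Effective convolution weights: with weight normalisation each output
# channel's kernel is its direction column scaled to norm g; otherwise V
# is used directly. Returns lists W, b and kernel sizes in the canonical
# order expected by the fused C++ pass.
effective_weights <- function(model) {
  convs <- model$convs
  W <- lapply(convs, function(cv) {
    if (is.null(cv$g)) return(cv$V)
    nrm <- sqrt(colSums(cv$V^2))
    scale <- ifelse(nrm > 0, cv$g / nrm, 0)
    sweep(cv$V, 2L, scale, `*`)
  })
  list(W = unname(W), b = unname(lapply(convs, `[[`, "b")),
       k = vapply(convs, `[[`, integer(1), "k", USE.NAMES = FALSE))
}

# Run the fused forward (and optionally backward) pass on one image.
# x: L x D matrix on the [0,1] scale; y, loss_mask: vectors of length L*D.
model_pass <- function(model, x, y = NULL, loss_mask = NULL,
                       loss_cfg = NULL, want_grad = FALSE) {
  eff <- effective_weights(model)
  L <- nrow(x); D <- ncol(x)
  if (is.null(y)) y <- numeric(L * D)
  if (is.null(loss_mask)) loss_mask <- numeric(L * D)
  eps <- if (is.null(loss_cfg)) 1e-4 else loss_cfg$epsilon
  kl <- if (is.null(loss_cfg)) 5 / 255 else loss_cfg$k
  wdsr_pass(as.vector(x) - model$mean_shift, L, D, eff$W, eff$b, eff$k,
            model$cfg$n_blocks, model$mean_shift, y, loss_mask, eps, kl,
            want_grad)
}

#' Predict the refined high-resolution image
#'
#' Applies the trained network to a cubic-up-sampled image. The model is
#' fully convolutional with same-padding, so any line/depth size is
#' accepted; prediction is deterministic and is applied to the whole image
#' (acquired lines may change too - there is no masking at inference).
#'
#' @param object A `wdsr_model`.
#' @param image Input `us_image` (unit range) or numeric matrix in `[0, 1]`.
#' @param clip Clamp the output to `[0, 1]` (default), the export
#'   convention for intensities.
#' @param ... Unused.
#' @return A `us_image` (unit range) with the input's mask and district.
#' @export
predict.wdsr_model <- function(object, image, clip = TRUE, ...) {
  px <- if (inherits(image, "us_image")) {
    convert_range(image, "unit")$pixels
  } else {
    pixel_matrix(image)
  }
  out <- model_pass(object, px)$yhat
  out <- matrix(out, nrow(px), ncol(px))
  if (clip) out <- pmin(pmax(out, 0), 1)
  us_image(out, "unit",
           acquired_mask = if (inherits(image, "us_image")) image$acquired_mask,
           district = district_of(image), strict = FALSE)
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single RDS file holding all parameter tensors, with
#' a JSON sidecar (`<path>.json`) recording the architecture configuration
#' and the trainable-parameter count.
#'
#' @param model A `wdsr_model`.
#' @param path Checkpoint path (conventionally `.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `wdsr_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "wdsr_model"))
  saveRDS(model, path, version = 3L)
  sidecar <- c(unclass(model$cfg),
               list(mean_shift = model$mean_shift,
                    parameter_count = model_parameter_count(model)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "wdsr_model"))
  model
}

#' @export
print.wdsr_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "<wdsr_model> %dX, %d blocks of width %d (x%d), kernel %dx%d, %s parameters\n",
    cfg$up_factor, cfg$n_blocks, cfg$n_feats, cfg$expansion,
    cfg$kernel_size, cfg$kernel_size,
    format(model_parameter_count(x), big.mark = ",")))
  invisible(x)
}
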