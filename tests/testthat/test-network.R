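test_that("closed-form parameter count matches instantiated models exactly", {
  for (up in c(2, 4)) {
    for (nf in c(4, 16, 48)) {
      for (ex in c(1, 3, 6)) {
        for (wn in c(TRUE, FALSE)) {
          cfg <- network_config(up, n_feats = nf, expansion = ex,
                                weight_norm = wn)
          set.seed(1)
          model <- build_network(cfg)
          expect_identical(count_parameters(cfg), model_parameter_count(model))
        }
      }
    }
  }
})

test_that("the pinned 2X width reproduces the 889K parameter budget", {
  n2 <- count_parameters(network_config(2))
  expect_equal(n2, 888989)
  expect_equal(round(n2 / 1000), 889)
})

test_that("per-convolution counts match a hand count without weight norm", {
  # 1x1 conv 1->1: one weight plus one bias; 5x5 skip: 25 weights + bias
  cpc <- beamsr:::conv_param_count
  expect_equal(cpc(1, 1, 1, FALSE), 2)
  expect_equal(cpc(5, 1, 1, FALSE), 26)
  expect_equal(cpc(3, 32, 192, TRUE), 3 * 3 * 32 * 192 + 192 + 192)
  # block count enters linearly
  c0 <- count_parameters(network_config(2, n_blocks = 0))
  c8 <- count_parameters(network_config(2, n_blocks = 8))
  c16 <- count_parameters(network_config(2, n_blocks = 16))
  expect_equal(c16 - c8, c8 - c0)
})

test_that("the network is shape-preserving for arbitrary input sizes", {
  model <- tiny_net()
  for (dims in list(c(16, 16), c(37, 29), c(8, 50))) {
    x <- matrix(runif(prod(dims)), dims[1], dims[2])
    out <- predict(model, x)
    expect_equal(dim(out), dims)
  }
})

test_that("an untrained model is the identity on its input", {
  # delta-kernel skip + silenced residual body => prediction == input
  model <- tiny_net()
  img <- random_test_image(24, 18, seed = 6)
  out <- predict(model, img, clip = FALSE)
  expect_equal(out$pixels, img$pixels, tolerance = 1e-6)
})

test_that("inference is deterministic and batch-packing invariant", {
  model <- tiny_net(seed = 11)
  imgs <- lapply(1:3, function(i) random_test_image(20, 20, seed = i))
  single <- lapply(imgs, function(im) predict(model, im)$pixels)
  again <- lapply(imgs, function(im) predict(model, im)$pixels)
  expect_identical(single, again)
  # processing as part of a sequence gives the same result as alone
  seq_out <- superresolve_video(
    lapply(imgs, function(im) downsample_beamlines(im, sampling_scheme(2))),
    model, sampling_scheme(2))
  alone <- lapply(imgs, function(im) {
    superresolve_image(downsample_beamlines(im, sampling_scheme(2)),
                       model, sampling_scheme(2))$prediction$pixels
  })
  expect_equal(lapply(seq_out$predictions, `[[`, "pixels"), alone,
               tolerance = 1e-6)
})

test_that("generic convolution gradients pass a finite-difference check", {
  set.seed(21)
  L <- 6; D <- 5; ci <- 2; co <- 3; k <- 3
  x <- array(rnorm(L * D * ci), c(L, D, ci))
  W <- matrix(rnorm(k * k * ci * co, sd = 0.3), k * k * ci, co)
  b <- rnorm(co)
  gy <- array(rnorm(L * D * co), c(L, D, co))
  loss_of <- function(Wp, xp) sum(beamsr:::conv2d_fwd(xp, Wp, b, k) * gy)
  g <- beamsr:::conv2d_bwd(x, W, gy, k)
  h <- 1e-6
  for (idx in sample(length(W), 8)) {
    Wp <- W; Wm <- W
    Wp[idx] <- Wp[idx] + h; Wm[idx] <- Wm[idx] - h
    num <- (loss_of(Wp, x) - loss_of(Wm, x)) / (2 * h)
    expect_equal(g$gW[idx], num, tolerance = 1e-5)
  }
  for (idx in sample(length(x), 8)) {
    xp <- x; xm <- x
    xp[idx] <- xp[idx] + h; xm[idx] <- xm[idx] - h
    num <- (loss_of(W, xp) - loss_of(W, xm)) / (2 * h)
    expect_equal(g$gx[idx], num, tolerance = 1e-5)
  }
})

test_that("the fused pass agrees with a layer-by-layer composition", {
  model <- tiny_net(seed = 31)
  # wake the residual body up so the test exercises non-trivial activations
  model$convs$tail$g <- 0.7
  img <- random_test_image(16, 12, seed = 32)
  eff <- beamsr:::effective_weights(model)
  x0 <- img$pixels - model$mean_shift
  as_cube <- function(m) array(m, c(dim(m), 1))
  conv <- function(x, i) {
    beamsr:::conv2d_fwd(x, eff$W[[i]], eff$b[[i]], eff$k[i])
  }
  h <- conv(as_cube(x0), 1)
  nb <- model$cfg$n_blocks
  for (i in seq_len(nb)) {
    t1 <- pmax(conv(h, 2 * i), 0)
    h <- h + conv(t1, 2 * i + 1)
  }
  body <- conv(h, 2 * nb + 2)
  skip <- conv(as_cube(x0), 2 * nb + 3)
  ref <- body[, , 1] + skip[, , 1] + model$mean_shift
  fused <- beamsr:::model_pass(model, img$pixels)$yhat
  expect_equal(matrix(fused, 16, 12), ref, tolerance = 1e-5)
})

test_that("training-loss gradients are finite and correct on a random batch", {
  model <- tiny_net(seed = 41)
  model$convs$tail$g <- 0.5
  img <- random_test_image(12, 10, seed = 42)
  target <- random_test_image(12, 10, seed = 43)
  lc <- loss_config(2)
  mask <- matrix(0, 12, 10)
  mask[beamsr:::loss_line_mask(12, lc), ] <- 1
  res <- beamsr:::model_pass(model, img$pixels, as.vector(target$pixels),
                             as.vector(mask), lc, want_grad = TRUE)
  expect_true(all(vapply(res$gW, function(g) all(is.finite(g)), logical(1))))
  expect_true(all(vapply(res$gb, function(g) all(is.finite(g)), logical(1))))
  # finite-difference check on a few effective-weight entries (single
  # precision forward => loose tolerance)
  eff <- beamsr:::effective_weights(model)
  loss_at <- function(eff) {
    beamsr:::wdsr_pass(as.vector(img$pixels) - model$mean_shift, 12, 10,
                       eff$W, eff$b, eff$k, model$cfg$n_blocks,
                       model$mean_shift, as.vector(target$pixels),
                       as.vector(mask), lc$epsilon, lc$k, FALSE)$loss
  }
  set.seed(44)
  for (layer in c(1, 3, length(eff$W))) {
    idx <- sample(length(eff$W[[layer]]), 2)
    for (i in idx) {
      h <- 1e-3
      ep <- eff; ep$W[[layer]][i] <- ep$W[[layer]][i] + h
      em <- eff; em$W[[layer]][i] <- em$W[[layer]][i] - h
      num <- (loss_at(ep) - loss_at(em)) / (2 * h)
      ana <- res$gW[[layer]][i]
      expect_lt(abs(ana - num) / max(1, abs(num)), 0.05)
    }
  }
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  model <- tiny_net(seed = 51)
  path <- file.path(tempdir(), "ckpt.rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$convs, model$convs)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$parameter_count, model_parameter_count(model))
  expect_equal(side$up_factor, 2)
  unlink(c(path, paste0(path, ".json")))
})

test_that("network config enforces the kernel-size rule", {
  expect_equal(network_config(2)$kernel_size, 3)
  expect_equal(network_config(4)$kernel_size, 5)
  expect_equal(network_config(4)$n_feats, 10)
  expect_error(network_config(3), "up_factor")
  expect_error(network_config(2, n_feats = 0), "n_feats")
})
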