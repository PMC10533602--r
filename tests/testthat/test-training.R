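test_that("masked log loss attains its closed-form minimum at zero error", {
  y <- random_test_image(16, 10, seed = 1)
  for (s in c(2, 4)) {
    lc <- loss_config(s)
    n_masked <- sum((0:15) %% s != 0) * 10
    expect_equal(masked_log_loss(y, y, lc),
                 n_masked * log(lc$epsilon / lc$k))
  }
  # the per-pixel term at zero error is about -5.279 with the defaults
  lc <- loss_config(2)
  expect_equal(log(lc$epsilon / lc$k), log(1e-4 * 255 / 5))
  expect_equal(log(lc$epsilon / lc$k), -5.27851, tolerance = 1e-5)
})

test_that("a masked pixel with error k - epsilon contributes exactly zero", {
  lc <- loss_config(2)
  y <- us_image(matrix(0.5, 8, 4), "unit")
  yhat <- y
  yhat$pixels[2, 3] <- 0.5 + (lc$k - lc$epsilon)  # line 1 (0-based) is masked
  n_masked <- 4 * 4
  expect_equal(masked_log_loss(y, yhat, lc),
               (n_masked - 1) * log(lc$epsilon / lc$k))
})

test_that("acquired lines neither contribute to the loss nor its gradient", {
  set.seed(13)
  y <- random_test_image(16, 8, seed = 14)
  yhat <- random_test_image(16, 8, seed = 15)
  lc <- loss_config(4)
  base <- masked_log_loss(y, yhat, lc)
  pert <- yhat
  acquired <- which((seq_len(16) - 1) %% 4 == 0)
  pert$pixels[acquired, ] <- runif(length(acquired) * 8)
  expect_identical(masked_log_loss(y, pert, lc), base)
  g <- masked_log_loss(y, yhat, lc, gradient = TRUE)$grad
  expect_true(all(g[acquired, ] == 0))
  expect_true(any(g[-acquired, ] != 0))
})

test_that("the loss increases monotonically with each masked pixel's error", {
  lc <- loss_config(2)
  y <- us_image(matrix(0.5, 8, 4), "unit")
  errs <- c(0, 0.001, 0.01, 0.05, 0.2)
  losses <- vapply(errs, function(e) {
    yh <- y; yh$pixels[2, 1] <- 0.5 + e
    masked_log_loss(y, yh, lc)
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("the literal residue-class mask covers mod(l, s) == 0 lines", {
  lc <- loss_config(2, mask_convention = "equation")
  # 1-based lines 2, 4, 6, 8 -> 0-based 1, 3, 5, 7
  expect_equal(which(beamsr:::loss_line_mask(8, lc)), c(2, 4, 6, 8))
  lc4 <- loss_config(4, mask_convention = "equation")
  expect_equal(which(beamsr:::loss_line_mask(8, lc4)), c(4, 8))
  # default: every non-acquired line
  lc_def <- loss_config(4)
  expect_equal(which(beamsr:::loss_line_mask(8, lc_def)), c(2, 3, 4, 6, 7, 8))
})

test_that("loss config validates its constants", {
  expect_error(loss_config(3), "`s`")
  expect_error(loss_config(2, epsilon = 0), "epsilon")
  expect_error(loss_config(2, k = 1e-5), "k")
})

test_that("the learning rate decays monotonically to the floor", {
  tc <- train_config(epochs = 50, lr_init = 1e-3, lr_floor = 1e-6)
  lrs <- lr_at_epoch(0:49, tc)
  expect_equal(lrs[1], 1e-3)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(lrs[50], 1e-6)
  expect_true(all(lrs >= 1e-6))
  expect_error(lr_at_epoch(50, tc), "epoch")
  expect_error(lr_at_epoch(-1, tc), "epoch")
  # the 200-epoch reference schedule also lands on the floor
  tc200 <- train_config(epochs = 200)
  expect_equal(lr_at_epoch(199, tc200), 1e-6)
})

test_that("weight-norm backward matches a finite-difference check", {
  set.seed(61)
  cv <- list(V = matrix(rnorm(12), 4, 3), g = rnorm(3), b = rep(0, 3))
  gW <- matrix(rnorm(12), 4, 3)
  wb <- beamsr:::weight_norm_backward(cv, gW)
  eff_of <- function(V, g) {
    sweep(V, 2, g / sqrt(colSums(V^2)), `*`)
  }
  h <- 1e-7
  for (idx in 1:6) {
    Vp <- cv$V; Vm <- cv$V
    Vp[idx] <- Vp[idx] + h; Vm[idx] <- Vm[idx] - h
    num <- sum(gW * (eff_of(Vp, cv$g) - eff_of(Vm, cv$g))) / (2 * h)
    expect_equal(wb$gV[idx], num, tolerance = 1e-4)
  }
  for (idx in 1:3) {
    gp <- cv$g; gm <- cv$g
    gp[idx] <- gp[idx] + h; gm[idx] <- gm[idx] - h
    num <- sum(gW * (eff_of(cv$V, gp) - eff_of(cv$V, gm))) / (2 * h)
    expect_equal(wb$gg[idx], num, tolerance = 1e-4)
  }
})

make_micro_pairs <- function(n, L = 24, D = 24, s = 2, seed = 70) {
  imgs <- generate_dataset(n, seed = seed, lines = L, depth = D)
  lapply(imgs, make_training_pair, scheme = sampling_scheme(s))
}

test_that("training is reproducible and makes progress on a small set", {
  pairs <- make_micro_pairs(12)
  tc <- train_config(epochs = 6, batch_size = 4, seed = 9)
  lc <- loss_config(2)
  fit1 <- train_network(tiny_net(seed = 9), pairs, tc, lc,
                        validation = pairs[1:2])
  fit2 <- train_network(tiny_net(seed = 9), pairs, tc, lc,
                        validation = pairs[1:2])
  expect_identical(fit1$history, fit2$history)
  expect_identical(predict(fit1$model, pairs[[1]]$input)$pixels,
                   predict(fit2$model, pairs[[1]]$input)$pixels)
  # optimisation makes progress from the identity baseline
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  expect_true(all(is.finite(fit1$history$val_psnr)))
})

test_that("training rejects inconsistent inputs", {
  pairs <- make_micro_pairs(2)
  expect_error(train_network(tiny_net(), list(), train_config(1),
                             loss_config(2)), "empty")
  expect_error(train_network(tiny_net(up_factor = 2), pairs,
                             train_config(1), loss_config(4)),
               "up-sampling factor")
})
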