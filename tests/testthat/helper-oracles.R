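# Independent brute-force reference implementations used to cross-check the
# package's vectorised code paths. These are deliberately written as scalar
# loops / recursions so they share no code with the implementation.

# Keys kernel evaluated pointwise from its piecewise polynomial.
oracle_keys <- function(x, a = -0.5) {
  x <- abs(x)
  if (x <= 1) (a + 2) * x^3 - (a + 3) * x^2 + 1
  else if (x < 2) a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a
  else 0
}

# Per-pixel cubic-convolution line interpolation with recursive quadratic
# boundary extension f(-1) = 3 f(0) - 3 f(1) + f(2).
oracle_upsample <- function(low, s, phase = 0, a = -0.5) {
  n <- nrow(low)
  line_at <- function(j) {
    if (j >= 0 && j < n) return(low[j + 1, ])
    if (j < 0) return(3 * line_at(j + 1) - 3 * line_at(j + 2) + line_at(j + 3))
    3 * line_at(j - 1) - 3 * line_at(j - 2) + line_at(j - 3)
  }
  out <- matrix(0, s * n, ncol(low))
  for (l in 0:(s * n - 1)) {
    u <- (l - phase) / s
    if (u == floor(u) && u >= 0 && u < n) {
      out[l + 1, ] <- low[u + 1, ]
    } else {
      acc <- numeric(ncol(low))
      for (j in (floor(u) - 1):(floor(u) + 2)) {
        acc <- acc + oracle_keys(u - j, a) * line_at(j)
      }
      out[l + 1, ] <- acc
    }
  }
  out
}

# Metric oracles from raw moments, elementwise loops.
oracle_mse <- function(A, B) {
  acc <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    acc <- acc + (A[i, j] - B[i, j])^2
  }
  acc / (nrow(A) * ncol(A))
}

oracle_psnr <- function(A, B) 10 * log10(max(A)^2 / oracle_mse(A, B))

oracle_mae <- function(A, B) {
  acc <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    acc <- acc + abs(A[i, j] - B[i, j])
  }
  acc / (nrow(A) * ncol(A))
}

oracle_ssim <- function(A, B, C1 = (0.01 * 255)^2, C2 = (0.03 * 255)^2,
                        C3 = C2 / 2) {
  n <- length(A)
  sA <- 0; sB <- 0; sAA <- 0; sBB <- 0; sAB <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    sA <- sA + A[i, j]; sB <- sB + B[i, j]
    sAA <- sAA + A[i, j]^2; sBB <- sBB + B[i, j]^2
    sAB <- sAB + A[i, j] * B[i, j]
  }
  muA <- sA / n; muB <- sB / n
  vA <- sAA / n - muA^2; vB <- sBB / n - muB^2
  cAB <- sAB / n - muA * muB
  l <- (2 * muA * muB + C1) / (muA^2 + muB^2 + C1)
  cc <- (2 * sqrt(vA) * sqrt(vB) + C2) / (vA + vB + C2)
  ss <- (cAB + C3) / (sqrt(vA) * sqrt(vB) + C3)
  l * cc * ss
}

# A small speckled test image without going through the full generator.
random_test_image <- function(L, D, seed) {
  set.seed(seed)
  us_image(matrix(runif(L * D), L, D), "unit")
}

# Tiny network configuration used wherever architecture size is irrelevant.
tiny_net <- function(up_factor = 2, seed = 1, mean_shift = 0.5) {
  cfg <- network_config(up_factor, n_feats = 4, expansion = 2, n_blocks = 2)
  set.seed(seed)
  build_network(cfg, mean_shift = mean_shift)
}
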