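#' Image quality metrics
#'
#' Global (whole-image) quality metrics used to compare a reconstruction
#' against its high-resolution target: mean squared error, peak
#' signal-to-noise ratio, structural similarity and mean absolute error.
#'
#' All error magnitudes are reported on the 0-255 grey scale: a `us_image`
#' with `"unit"` range is denormalised (multiplied by 255) before the
#' computation, so thresholds such as "error below 5 grey levels" have
#' their usual meaning. Bare numeric matrices are used as-is, on whatever
#' scale they carry.
#'
#' `us_psnr` uses the maximum of its *first* (target) argument as the peak,
#' so the argument order matters: target first, reconstruction second. A
#' zero-MSE pair returns `Inf`.
#'
#' SSIM is the product of luminance, contrast and structure terms
#' `l = (2 mu_A mu_B + C1) / (mu_A^2 + mu_B^2 + C1)`,
#' `c = (2 sd_A sd_B + C2) / (sd_A^2 + sd_B^2 + C2)`,
#' `s = (cov_AB + C3) / (sd_A sd_B + C3)`,
#' computed from population moments over a single global window by
#' default; `window` switches to a uniform sliding-window mean of local
#' SSIM values. Stabilising constants default to `C1 = (0.01 R)^2`,
#' `C2 = (0.03 R)^2`, `C3 = C2 / 2` with `R` the dynamic range (255 here).
#'
#' @param a Target image (`us_image` or numeric matrix).
#' @param b Reconstructed image, same dimensions.
#' @param C1,C2,C3 SSIM stabilising constants; defaults as above.
#' @param window Optional odd window size for sliding-window SSIM; `NULL`
#'   (default) computes a single global SSIM.
#' @return A single numeric value (`us_psnr` in dB; `us_mse`/`us_mae` in
#'   squared / plain grey levels; `us_ssim` unitless in `[-1, 1]`).
#' @name metrics
NULL

# Denormalise to the 0-255 scale on which all error magnitudes are quoted.
metric_matrix <- function(x) {
  if (inherits(x, "us_image")) {
    if (x$value_range == "unit") x$pixels * 255 else x$pixels
  } else {
    pixel_matrix(x)
  }
}

check_same_dim <- function(A, B) {
  if (!all(dim(A) == dim(B))) {
    stop(sprintf("image dimensions differ: %dx%d vs %dx%d",
                 nrow(A), ncol(A), nrow(B), ncol(B)))
  }
}

#' @rdname metrics
#' @export
us_mse <- function(a, b) {
  A <- metric_matrix(a); B <- metric_matrix(b)
  check_same_dim(A, B)
  mean((A - B)^2)
}

#' @rdname metrics
#' @export
us_psnr <- function(a, b) {
  A <- metric_matrix(a); B <- metric_matrix(b)
  check_same_dim(A, B)
  peak <- max(A)
  err <- mean((A - B)^2)
  if (err == 0) return(Inf)
  if (peak <= 0) stop("degenerate target: max(A) is not positive")
  10 * log10(peak^2 / err)
}

#' @rdname metrics
#' @export
us_ssim <- function(a, b, C1 = (0.01 * 255)^2, C2 = (0.03 * 255)^2,
                    C3 = C2 / 2, window = NULL) {
  A <- metric_matrix(a); B <- metric_matrix(b)
  check_same_dim(A, B)
  if (is.null(window)) return(ssim_global(A, B, C1, C2, C3))
  if (window %% 2 != 1 || window < 3) stop("`window` must be odd and >= 3")
  r <- (window - 1) / 2
  vals <- c()
  idx_i <- seq(1 + r, nrow(A) - r)
  idx_j <- seq(1 + r, ncol(A) - r)
  if (length(idx_i) == 0 || length(idx_j) == 0) {
    stop("image smaller than the SSIM window")
  }
  vals <- matrix(NA_real_, length(idx_i), length(idx_j))
  for (ii in seq_along(idx_i)) {
    for (jj in seq_along(idx_j)) {
      wi <- (idx_i[ii] - r):(idx_i[ii] + r)
      wj <- (idx_j[jj] - r):(idx_j[jj] + r)
      vals[ii, jj] <- ssim_global(A[wi, wj], B[wi, wj], C1, C2, C3)
    }
  }
  mean(vals)
}

# Single-window SSIM from population moments.
ssim_global <- function(A, B, C1, C2, C3) {
  n <- length(A)
  muA <- mean(A); muB <- mean(B)
  vA <- mean((A - muA)^2); vB <- mean((B - muB)^2)
  sAB <- mean((A - muA) * (B - muB))
  sA <- sqrt(vA); sB <- sqrt(vB)
  l <- (2 * muA * muB + C1) / (muA^2 + muB^2 + C1)
  cc <- (2 * sA * sB + C2) / (vA + vB + C2)
  ss <- (sAB + C3) / (sA * sB + C3)
  l * cc * ss
}

#' @rdname metrics
#' @export
us_mae <- function(a, b) {
  A <- metric_matrix(a); B <- metric_matrix(b)
  check_same_dim(A, B)
  mean(abs(A - B))
}

#' Pointwise absolute-error image
#'
#' Elementwise `|A - B|` on the 0-255 grey scale, together with its maximum
#' value (the number conventionally quoted next to an error image).
#'
#' @param a,b Images of identical dimensions (`us_image` or matrix).
#' @return A list with `image` (numeric matrix of absolute errors) and
#'   `max` (its maximum).
#' @export
error_image <- function(a, b) {
  A <- metric_matrix(a); B <- metric_matrix(b)
  check_same_dim(A, B)
  e <- abs(A - B)
  list(image = e, max = max(e))
}

#' Histogram of absolute reconstruction errors
#'
#' Counts pixels by absolute error in half-open bins
#' `[0, w), [w, 2w), ...` on the 0-255 scale. The first bin (default
#' errors strictly below 5 grey levels) counts the pixels that are
#' visually indistinguishable from the target.
#'
#' @param a,b Images of identical dimensions.
#' @param bin_width Bin width in grey levels (default 5).
#' @return Integer vector of counts, one per bin, with the bin left edges
#'   as names and attributes `breaks` and `first_bin`.
#' @export
error_histogram <- function(a, b, bin_width = 5) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  e <- error_image(a, b)$image
  idx <- floor(e / bin_width)          # half-open bins: "lower than" strict
  nbin <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nbin)
  breaks <- bin_width * (0:nbin)
  names(counts) <- breaks[-length(breaks)]
  structure(counts, breaks = breaks, first_bin = counts[[1]])
}

#' Tukey box-plot summary of a metric over a test cohort
#'
#' Median, quartiles (linear-interpolation quantiles, type 7) and Tukey
#' whiskers: the most extreme observations within 1.5 IQR of the quartile.
#'
#' @param values Nonempty numeric vector (one metric value per image).
#' @return A list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`
#'   and `n`.
#' @export
cohort_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("`values` must contain finite entries")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- min(values[values >= q[1] - 1.5 * iqr])
  hi <- max(values[values <= q[3] + 1.5 * iqr])
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = lo, whisker_high = hi, n = length(values))
}

#' Mean image brightness
#'
#' The average of all pixel intensities, on the image's own scale.
#'
#' @param a A `us_image` or numeric matrix.
#' @return Mean intensity.
#' @export
brightness <- function(a) mean(pixel_matrix(a))

#' Write a per-image metrics table and cohort summary
#'
#' Emits the per-image records as CSV and the cohort box-plot statistics
#' as JSON, the report format produced by [run_experiment()].
#'
#' @param per_image Data frame of per-image metric records.
#' @param cohort Named list of cohort summaries.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_metrics_report <- function(per_image, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "per_image_metrics.csv")
  json <- file.path(dir, "cohort_summary.json")
  write.csv(per_image, csv, row.names = FALSE)
  jsonlite::write_json(cohort, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, json = json))
}
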