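#' Beamline sampling scheme
#'
#' Describes how a low-resolution acquisition relates to the full line
#' grid: every `factor`-th lateral line is physically acquired (starting at
#' line `phase`), and the missing lines are reconstructed by 1-D cubic
#' convolution along the lateral axis. The depth axis is never resampled.
#'
#' @param factor Decimation/up-sampling factor `s`: 1 (identity), 2 or 4.
#' @param phase Index (0-based) of the first acquired line, `0 <= phase < s`.
#' @param kernel_a Free parameter of the Keys cubic kernel; must be
#'   negative. The default -0.5 gives quadratic reproduction precision.
#' @param boundary Edge-extension rule for interpolation near the image
#'   borders; `"quadratic"` extrapolates with
#'   `f(-1) = 3 f(0) - 3 f(1) + f(2)` (mirrored at the far edge), which
#'   preserves the kernel's polynomial precision at the boundary.
#'
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(factor, phase = 0L, kernel_a = -0.5,
                            boundary = "quadratic") {
  factor <- as.integer(factor)
  phase <- as.integer(phase)
  if (!factor %in% c(1L, 2L, 4L)) stop("`factor` must be 1, 2 or 4")
  if (phase < 0L || phase >= factor) stop("`phase` must satisfy 0 <= phase < factor")
  if (!is.numeric(kernel_a) || kernel_a >= 0) stop("`kernel_a` must be negative")
  boundary <- match.arg(boundary, "quadratic")
  structure(list(factor = factor, phase = phase, kernel_a = kernel_a,
                 boundary = boundary),
            class = "sampling_scheme")
}

#' Keys cubic convolution kernel
#'
#' The piecewise-cubic interpolating kernel with 4-sample support:
#' `(a+2)|x|^3 - (a+3)|x|^2 + 1` for `|x| <= 1`,
#' `a|x|^3 - 5a|x|^2 + 8a|x| - 4a` for `1 < |x| < 2`, and 0 beyond.
#' With `a = -0.5` the kernel reproduces quadratic polynomials exactly.
#'
#' @param x Numeric vector of offsets (in units of the sample spacing).
#' @param a Kernel free parameter (default -0.5).
#' @return Kernel weights, same length as `x`.
#' @export
cubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  w <- numeric(length(ax))
  near <- ax <= 1
  mid <- ax > 1 & ax < 2
  w[near] <- (a + 2) * ax[near]^3 - (a + 3) * ax[near]^2 + 1
  w[mid] <- a * ax[mid]^3 - 5 * a * ax[mid]^2 + 8 * a * ax[mid] - 4 * a
  w
}

# Trailing-crop an image so its line count is divisible by s.
crop_to_factor <- function(img, s) {
  px <- pixel_matrix(img)
  keep <- (nrow(px) %/% s) * s
  if (keep == nrow(px)) return(img)
  if (inherits(img, "us_image")) {
    us_image(px[seq_len(keep), , drop = FALSE], img$value_range,
             img$acquired_mask[seq_len(keep)], img$district, strict = FALSE)
  } else {
    px[seq_len(keep), , drop = FALSE]
  }
}

#' Decimate lateral beamlines
#'
#' Emulates a fast low-resolution acquisition by keeping only the lines a
#' reduced probe would fire: those with `(l - phase) mod s == 0` (0-based
#' line index `l`). If the line count is not divisible by `s`, trailing
#' lines are cropped first. The depth axis is untouched.
#'
#' @param img A `us_image` (or numeric matrix).
#' @param scheme A [sampling_scheme()].
#' @return A `us_image` with `L/s` lines, all flagged as acquired.
#' @export
downsample_beamlines <- function(img, scheme) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  s <- scheme$factor
  px <- pixel_matrix(img)
  if (s == 1L) {
    return(us_image(px, value_range_of(img), district = district_of(img),
                    strict = FALSE))
  }
  if (nrow(px) < 2L * s) {
    stop(sprintf("image too narrow for decimation: %d lines < 2 * %d",
                 nrow(px), s))
  }
  img <- crop_to_factor(img, s)
  px <- pixel_matrix(img)
  keep <- which((seq_len(nrow(px)) - 1L - scheme$phase) %% s == 0L)
  us_image(px[keep, , drop = FALSE], value_range_of(img),
           district = district_of(img), strict = FALSE)
}

value_range_of <- function(img) {
  if (inherits(img, "us_image")) img$value_range else "unit"
}
district_of <- function(img) {
  if (inherits(img, "us_image")) img$district else NULL
}

# Extend a line stack by two extrapolated lines on each side using the
# quadratic rule f(-1) = 3 f(0) - 3 f(1) + f(2), applied recursively.
extend_lines <- function(px) {
  n <- nrow(px)
  lo1 <- 3 * px[1, ] - 3 * px[2, ] + px[3, ]
  lo2 <- 3 * lo1 - 3 * px[1, ] + px[2, ]
  hi1 <- 3 * px[n, ] - 3 * px[n - 1, ] + px[n - 2, ]
  hi2 <- 3 * hi1 - 3 * px[n, ] + px[n - 1, ]
  rbind(lo2, lo1, px, hi1, hi2, deparse.level = 0)
}

#' Reconstruct full lateral resolution by cubic convolution
#'
#' Inserts the missing beamlines of a decimated image by 1-D Keys cubic
#' interpolation along the lateral axis, depth sample by depth sample.
#' Lines at acquired grid positions are copied bit-exactly from the input;
#' each missing line is the kernel-weighted sum of the 4 nearest acquired
#' lines, with quadratic extrapolation supplying virtual lines beyond the
#' image borders. Interpolated intensities are left unclamped (cubic
#' kernels can overshoot near sharp interfaces); clamping happens at
#' export.
#'
#' @param lowres A `us_image` (or matrix) holding the acquired lines.
#' @param scheme A [sampling_scheme()].
#' @param target_lines Number of output lines; must equal
#'   `scheme$factor * n_lines(lowres)`.
#' @return A `us_image` with `target_lines` lines whose `acquired_mask`
#'   distinguishes probe lines from interpolated lines.
#' @export
upsample_beamlines <- function(lowres, scheme,
                               target_lines = scheme$factor * n_lines(lowres)) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  s <- scheme$factor
  px <- pixel_matrix(lowres)
  n_low <- nrow(px)
  if (target_lines != s * n_low) {
    stop("`target_lines` must equal factor * n_lines(lowres)")
  }
  if (s == 1L) {
    return(us_image(px, value_range_of(lowres),
                    district = district_of(lowres), strict = FALSE))
  }
  if (n_low < 4L) {
    stop("insufficient support: cubic interpolation needs at least 4 acquired lines")
  }
  ext <- extend_lines(px)  # rows are low-res coordinates -2 .. n_low + 1
  out <- matrix(0, target_lines, ncol(px))
  acquired <- rep(FALSE, target_lines)
  for (l in seq_len(target_lines) - 1L) {
    u <- (l - scheme$phase) / s
    if (u == floor(u) && u >= 0 && u < n_low) {
      out[l + 1L, ] <- px[u + 1L, ]
      acquired[l + 1L] <- TRUE
    } else {
      i <- floor(u)
      j <- i + (-1L:2L)                     # 4-sample support
      w <- cubic_kernel(u - j, scheme$kernel_a)
      out[l + 1L, ] <- w %*% ext[j + 3L, , drop = FALSE]
    }
  }
  us_image(out, value_range_of(lowres), acquired_mask = acquired,
           district = district_of(lowres), strict = FALSE)
}

#' Build one (input, target) training pair
#'
#' Crops the high-resolution image to a line count divisible by the
#' decimation factor, decimates it, and re-expands it by cubic convolution.
#' The up-sampled image and the cropped original have identical dimensions
#' and form the network's input and target; the input's `acquired_mask`
#' records which lines the probe would really have fired.
#'
#' @param hr High-resolution `us_image` (or matrix).
#' @param scheme A [sampling_scheme()].
#' @return A list with elements `input` and `target` (both `us_image`).
#' @export
make_training_pair <- function(hr, scheme) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  hr <- crop_to_factor(hr, scheme$factor)
  target <- if (inherits(hr, "us_image")) hr
            else us_image(hr, "unit", strict = FALSE)
  low <- downsample_beamlines(target, scheme)
  input <- upsample_beamlines(low, scheme, n_lines(target))
  list(input = input, target = target)
}
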