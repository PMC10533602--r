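#' Synthetic speckle-phantom recipe
#'
#' Describes a synthetic B-mode-like image: a complex Gaussian scatterer
#' field (fully developed speckle) scaled by a per-region echogenicity
#' map, convolved with a separable point-spread function (lateral
#' Gaussian; axial Gaussian modulated by a carrier), envelope-detected,
#' log-compressed over a fixed dynamic range and normalised to `[0, 1]`.
#' Smooth elliptical inclusions emulate anatomical structure, and a
#' brightness offset emulates gain differences between acquisitions.
#'
#' @param lines,depth Image dimensions (L beamlines x D depth samples),
#'   each at least 16.
#' @param scatterer_density Expected scatterer energy per pixel; scales the
#'   scatterer amplitude variance.
#' @param psf_lateral_sigma,psf_axial_sigma Gaussian point-spread-function
#'   widths in pixels. A lateral width of at least one line spacing makes
#'   the speckle laterally smooth, mirroring lateral resolution being lower
#'   than axial resolution in real probes.
#' @param axial_carrier_period Period (pixels) of the cosine carrier
#'   modulating the axial PSF, mimicking the RF pulse.
#' @param inclusions List of inclusions from [inclusion()]; each must lie
#'   inside the image.
#' @param log_compression_db Displayed dynamic range in dB; envelopes below
#'   `max/10^(dB/20)` clip to black.
#' @param brightness_offset Mean-intensity shift added after compression
#'   (result re-clipped to `[0, 1]`).
#' @param seed Integer seed; the same spec and seed reproduce the image
#'   exactly.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(lines = 64L, depth = 64L, scatterer_density = 1,
                         psf_lateral_sigma = 1.5, psf_axial_sigma = 1,
                         axial_carrier_period = 4, inclusions = list(),
                         log_compression_db = 50, brightness_offset = 0,
                         seed = 1L) {
  lines <- as.integer(lines); depth <- as.integer(depth)
  if (lines < 16L || depth < 16L) stop("phantom dimensions must be >= 16")
  if (scatterer_density <= 0) stop("`scatterer_density` must be positive")
  if (log_compression_db <= 0) stop("`log_compression_db` must be positive")
  for (inc in inclusions) {
    stopifnot(inherits(inc, "phantom_inclusion"))
    if (inc$centre[1] - inc$axes[1] < 1 || inc$centre[1] + inc$axes[1] > lines ||
        inc$centre[2] - inc$axes[2] < 1 || inc$centre[2] + inc$axes[2] > depth) {
      stop("inclusion extends outside the image")
    }
  }
  structure(list(lines = lines, depth = depth,
                 scatterer_density = scatterer_density,
                 psf_lateral_sigma = psf_lateral_sigma,
                 psf_axial_sigma = psf_axial_sigma,
                 axial_carrier_period = axial_carrier_period,
                 inclusions = inclusions,
                 log_compression_db = log_compression_db,
                 brightness_offset = brightness_offset,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Elliptical inclusion of a phantom
#'
#' @param centre Numeric `(line, depth)` centre, in pixels (1-based).
#' @param axes Numeric `(lateral, axial)` semi-axes, in pixels.
#' @param echogenicity Scatterer-amplitude multiplier inside the ellipse
#'   (> 1 hyperechoic, < 1 hypoechoic).
#' @return An object of class `phantom_inclusion`.
#' @export
inclusion <- function(centre, axes, echogenicity) {
  stopifnot(length(centre) == 2, length(axes) == 2, all(axes > 0),
            echogenicity >= 0)
  structure(list(centre = as.numeric(centre), axes = as.numeric(axes),
                 echogenicity = echogenicity),
            class = "phantom_inclusion")
}

# Per-pixel scatterer-amplitude multiplier: 1 in the background, the
# inclusion's echogenicity inside it, with a ~1-pixel soft edge emulating
# acoustic interface blur.
echogenicity_map <- function(spec, offsets = c(0, 0)) {
  emap <- matrix(1, spec$lines, spec$depth)
  li <- seq_len(spec$lines); dj <- seq_len(spec$depth)
  for (inc in spec$inclusions) {
    c1 <- inc$centre[1] + offsets[1]; c2 <- inc$centre[2] + offsets[2]
    r <- sqrt(outer(((li - c1) / inc$axes[1])^2,
                    ((dj - c2) / inc$axes[2])^2, `+`))
    w <- pmin(pmax((1 - r) * min(inc$axes) + 0.5, 0), 1)
    emap <- emap * (1 + (inc$echogenicity - 1) * w)
  }
  emap
}

gaussian_taps <- function(sigma, modulate_period = NULL) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  if (!is.null(modulate_period)) k <- k * cos(2 * pi * x / modulate_period)
  k
}

# Band matrix applying a 1-D kernel along an axis of length n (zero-padded
# linear convolution), so filtering is K_lat %*% X %*% t(K_ax).
band_matrix <- function(n, taps) {
  r <- (length(taps) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    keep <- idx + o >= 1L & idx + o <= n
    K[cbind(idx[keep], (idx + o)[keep])] <- taps[o + r + 1L]
  }
  K
}

#' Generate one synthetic speckle phantom
#'
#' Draws the complex scatterer field, applies the separable PSF, detects
#' the envelope and log-compresses it (see [phantom_spec()]). With no
#' inclusions the pre-compression envelope has pointwise Rayleigh
#' statistics, the signature of fully developed speckle.
#'
#' @param spec A [phantom_spec()].
#' @param return_envelope Also return the pre-compression envelope matrix
#'   (used for speckle-statistics checks).
#' @return A `us_image` (unit range), or with `return_envelope = TRUE` a
#'   list with `image` and `envelope`.
#' @export
generate_phantom <- function(spec, return_envelope = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  field <- with_seed(spec$seed, random_field(spec))
  render_phantom(spec, field, return_envelope = return_envelope)
}

random_field <- function(spec) {
  n <- spec$lines * spec$depth
  amp <- sqrt(spec$scatterer_density)
  matrix(complex(real = rnorm(n), imaginary = rnorm(n)) * amp,
         spec$lines, spec$depth)
}

# Deterministic rendering of a scatterer field: echogenicity scaling, PSF
# convolution, envelope detection, log compression, brightness shift.
render_phantom <- function(spec, field, offsets = c(0, 0),
                           return_envelope = FALSE) {
  emap <- echogenicity_map(spec, offsets)
  Klat <- band_matrix(spec$lines, gaussian_taps(spec$psf_lateral_sigma))
  Kax <- band_matrix(spec$depth,
                     gaussian_taps(spec$psf_axial_sigma,
                                   spec$axial_carrier_period))
  scat <- emap * field
  resp <- Klat %*% Re(scat) %*% t(Kax) +
    1i * (Klat %*% Im(scat) %*% t(Kax))
  env <- Mod(resp)
  emax <- max(env)
  db <- spec$log_compression_db
  img <- pmax(1 + 20 * log10(pmax(env / emax, 1e-300)) / db, 0)
  img <- pmin(pmax(img + spec$brightness_offset, 0), 1)
  out <- us_image(img, "unit", district = "phantom")
  if (return_envelope) list(image = out, envelope = env) else out
}

#' Generate a data set of randomised phantoms
#'
#' Produces `n` images with randomised inclusion geometry and brightness.
#' Image `i` is generated entirely from its own sub-seed (`seed + 7919 i`),
#' so images are seed-isolated: regenerating any one of them does not
#' depend on, or perturb, the others.
#'
#' The default sampler draws 1-3 elliptical inclusions with uniform
#' centres (inside a margin), semi-axes between 4 pixels and a quarter of
#' the image, log-uniform echogenicity between 0.3 and 3, and a brightness
#' offset uniform on `[-0.1, 0.1]` -- a spread wide enough to exercise
#' brightness robustness of the trained network.
#'
#' @param n Number of images (>= 1).
#' @param spec_sampler Optional `function(seed)` returning a
#'   [phantom_spec()] for one image; overrides the default sampler.
#' @param seed Base seed.
#' @param lines,depth Dimensions passed to the default sampler.
#' @return List of `n` `us_image` objects.
#' @export
generate_dataset <- function(n, spec_sampler = NULL, seed = 1L,
                             lines = 64L, depth = 64L) {
  if (n < 1) stop("`n` must be >= 1")
  if (is.null(spec_sampler)) {
    spec_sampler <- function(s) default_phantom_sampler(s, lines, depth)
  }
  lapply(seq_len(n), function(i) {
    sub_seed <- as.integer(seed + 7919L * i)
    generate_phantom(spec_sampler(sub_seed))
  })
}

default_phantom_sampler <- function(seed, lines, depth) {
  with_seed(seed * 2L + 1L, {
    n_inc <- sample(1:3, 1)
    incs <- lapply(seq_len(n_inc), function(j) {
      ax <- runif(2, 4, min(lines, depth) / 4)
      ctr <- c(runif(1, 1 + ax[1], lines - ax[1]),
               runif(1, 1 + ax[2], depth - ax[2]))
      inclusion(ctr, ax, exp(runif(1, log(0.3), log(3))))
    })
    phantom_spec(lines = lines, depth = depth, inclusions = incs,
                 brightness_offset = runif(1, -0.1, 0.1), seed = seed)
  })
}

#' Generate a synthetic ultrasound video
#'
#' Renders `frames` images from a single frozen scatterer field while
#' translating the inclusions along a motion path, so an anatomical
#' feature moves across frames over a temporally coherent speckle texture
#' (as when structures move under a stationary probe).
#'
#' @param spec A [phantom_spec()] with at least one inclusion to move.
#' @param frames Number of frames `T >= 2` (with `T = 1` the result is a
#'   single [generate_phantom()] frame).
#' @param motion Either a length-2 `(lines, depth)` per-frame displacement
#'   (constant velocity), or a `frames x 2` matrix of absolute offsets
#'   applied to every inclusion centre.
#' @return List of `frames` `us_image` objects.
#' @export
generate_video <- function(spec, frames, motion = c(0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  frames <- as.integer(frames)
  if (frames < 1L) stop("`frames` must be >= 1")
  offsets <- if (is.matrix(motion)) {
    stopifnot(nrow(motion) == frames, ncol(motion) == 2)
    motion
  } else {
    stopifnot(length(motion) == 2)
    outer(seq_len(frames) - 1, as.numeric(motion))
  }
  for (t in seq_len(frames)) {
    for (inc in spec$inclusions) {
      c1 <- inc$centre[1] + offsets[t, 1]; c2 <- inc$centre[2] + offsets[t, 2]
      if (c1 - inc$axes[1] < 1 || c1 + inc$axes[1] > spec$lines ||
          c2 - inc$axes[2] < 1 || c2 + inc$axes[2] > spec$depth) {
        stop(sprintf("motion pushes an inclusion out of frame at frame %d", t))
      }
    }
  }
  field <- with_seed(spec$seed, random_field(spec))
  lapply(seq_len(frames), function(t) {
    render_phantom(spec, field, offsets = offsets[t, ])
  })
}
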