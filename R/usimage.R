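#' Grayscale ultrasound image container
#'
#' A B-mode image is stored as a numeric matrix whose first dimension is the
#' lateral axis (one row per beamline, `L` rows) and whose second dimension
#' is the axial/depth axis (`D` samples per line). The container carries the
#' nominal intensity scale, a per-line flag saying whether each beamline was
#' physically acquired by the probe or interpolated, and a free-form
#' anatomical district tag.
#'
#' @param pixels Numeric `L x D` matrix of grey intensities; rows are
#'   lateral beamlines, columns are depth samples.
#' @param value_range `"unit"` for intensities on `[0, 1]` (the scale used
#'   throughout training) or `"byte"` for raw `[0, 255]` data.
#' @param acquired_mask Logical vector of length `L`; `TRUE` marks lines
#'   physically acquired by the probe. Defaults to all `TRUE`.
#' @param district Optional free-form label (e.g. `"cardiac"`).
#'
#' @details A heavily decimated acquisition can legitimately hold as few as
#'   two lines, so the container itself only requires a nonempty grid;
#'   stages with stronger needs (cubic interpolation requires 4 acquired
#'   lines) enforce their own minima.
#' @param strict If `TRUE` (default) intensities must lie inside the
#'   declared range. Interpolation stages construct images with
#'   `strict = FALSE` because cubic kernels can overshoot the data range by
#'   a few percent near sharp interfaces; such values are only clamped when
#'   the image is exported.
#'
#' @return An object of class `us_image`.
#' @export
us_image <- function(pixels, value_range = c("unit", "byte"),
                     acquired_mask = NULL, district = NULL, strict = TRUE) {
  value_range <- match.arg(value_range)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix (lines x depth)")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("`pixels` must have at least one line and one depth sample")
  }
  if (any(!is.finite(pixels))) stop("`pixels` contains non-finite values")
  hi <- range_max(value_range)
  if (strict && (min(pixels) < 0 || max(pixels) > hi)) {
    stop(sprintf("intensities outside the declared '%s' range [0, %g]",
                 value_range, hi))
  }
  if (is.null(acquired_mask)) acquired_mask <- rep(TRUE, nrow(pixels))
  if (!is.logical(acquired_mask) || length(acquired_mask) != nrow(pixels)) {
    stop("`acquired_mask` must be a logical vector with one entry per line")
  }
  structure(
    list(pixels = unname(pixels), value_range = value_range,
         acquired_mask = acquired_mask, district = district),
    class = "us_image"
  )
}

range_max <- function(value_range) if (value_range == "byte") 255 else 1

#' @export
as.matrix.us_image <- function(x, ...) x$pixels

# Accept either a us_image or a bare matrix where only pixel values matter.
pixel_matrix <- function(x) {
  if (inherits(x, "us_image")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a `us_image` or a numeric matrix")
}

#' @export
dim.us_image <- function(x) dim(x$pixels)

#' Number of beamlines (lateral size) of an image
#' @param img A `us_image` or numeric matrix.
#' @return Integer line count.
#' @export
n_lines <- function(img) nrow(pixel_matrix(img))

#' Number of depth samples (axial size) of an image
#' @param img A `us_image` or numeric matrix.
#' @return Integer depth-sample count.
#' @export
n_depth <- function(img) ncol(pixel_matrix(img))

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf(
    "<us_image> %d lines x %d depth samples, range '%s', %d/%d lines acquired%s\n",
    nrow(x$pixels), ncol(x$pixels), x$value_range,
    sum(x$acquired_mask), length(x$acquired_mask),
    if (is.null(x$district)) "" else paste0(", district '", x$district, "'")))
  invisible(x)
}

# Rescale intensities between the "unit" and "byte" conventions.
convert_range <- function(img, value_range) {
  stopifnot(inherits(img, "us_image"))
  if (img$value_range == value_range) return(img)
  f <- if (value_range == "byte") 255 else 1 / 255
  us_image(img$pixels * f, value_range, img$acquired_mask, img$district,
           strict = FALSE)
}

# ---------------------------------------------------------------------------
# File I/O

#' Read a grayscale PNG or TIFF image as a `us_image`
#'
#' The first dimension of the stored raster is taken as the lateral axis.
#' Multi-channel files are averaged to one grey channel. 8- and 16-bit
#' files are supported; intensities are returned on the requested scale.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param value_range Scale of the returned image, `"unit"` or `"byte"`.
#' @param district Optional district tag attached to the result.
#' @return A `us_image`.
#' @export
read_us_image <- function(path, value_range = c("unit", "byte"),
                          district = NULL) {
  value_range <- match.arg(value_range)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(raw)) == 3L) raw <- rowMeans(raw, dims = 2L)
  px <- if (value_range == "byte") raw * 255 else raw
  us_image(px, value_range, district = district)
}

#' Write a `us_image` to PNG or TIFF
#'
#' Intensities are clamped to the declared range and quantised only here,
#' at export; the analysis pipeline holds real-valued intensities
#' throughout. PNG output is 8-bit; TIFF supports 8 or 16 bits per sample.
#'
#' @param img A `us_image`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth 8 or 16 (16 only for TIFF).
#' @return `path`, invisibly.
#' @export
write_us_image <- function(img, path, bit_depth = 8L) {
  stopifnot(inherits(img, "us_image"))
  u <- convert_range(img, "unit")$pixels
  u <- pmin(pmax(u, 0), 1)
  levels <- 2^bit_depth - 1
  u <- round(u * levels) / levels
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8L) stop("PNG export is 8-bit; use TIFF for 16-bit")
    png::writePNG(u, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!bit_depth %in% c(8L, 16L)) stop("TIFF bit depth must be 8 or 16")
    tiff::writeTIFF(u, path, bits.per.sample = as.integer(bit_depth))
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

#' Save or load a batch of images as a lossless tensor archive
#'
#' Stores full double-precision pixel tensors with their acquired-line
#' masks, value ranges and district tags, so training batches round-trip
#' exactly (unlike quantised PNG/TIFF export).
#'
#' @param images List of `us_image` objects.
#' @param path Archive path (conventionally `.rds`).
#' @return `save_us_batch` returns `path` invisibly; `load_us_batch`
#'   returns the list of `us_image` objects.
#' @export
save_us_batch <- function(images, path) {
  stopifnot(all(vapply(images, inherits, logical(1), "us_image")))
  saveRDS(images, path, version = 3L)
  invisible(path)
}

#' @rdname save_us_batch
#' @export
load_us_batch <- function(path) {
  images <- readRDS(path)
  stopifnot(all(vapply(images, inherits, logical(1), "us_image")))
  images
}
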