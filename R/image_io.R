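#' Construct an 8-bit grayscale image
#'
#' The codec's input/output unit: an integer matrix of pixel intensities in
#' \[0, 255\], with `m >= 1` rows and `n >= 1` columns.
#'
#' @param pixels Numeric matrix of integer-valued intensities in \[0, 255\].
#' @param dpi Optional integer resolution metadata (dots per inch).
#' @return An object of class `gray_image`: an integer matrix with an
#'   optional `dpi` attribute.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' dim(img)
#' @export
gray_image <- function(pixels, dpi = NULL) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop_argument("pixels must be a matrix with at least one row and column")
  }
  p <- as.numeric(pixels)
  if (anyNA(p) || any(p != floor(p)) || any(p < 0) || any(p > 255)) {
    stop_argument("pixel intensities must be integers in [0, 255]")
  }
  out <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  if (!is.null(dpi)) attr(out, "dpi") <- as.integer(dpi)
  class(out) <- c("gray_image", class(out))
  out
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, intensity range [%d, %d]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

as_gray_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "dpi") <- NULL
  m
}

#' Read an 8-bit grayscale image from PNG or TIFF
#'
#' Multi-channel (RGB/RGBA) inputs are converted to luminance with the
#' ITU-R BT.601 weights (0.299 R + 0.587 G + 0.114 B) and rounded. Images
#' with bit depth above 8 are rejected rather than silently rescaled, so
#' that rate and distortion accounting stays on the 8-bit scale.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [gray_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_io("cannot read image: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    dat <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop_io("cannot read PNG '%s': %s", path, conditionMessage(e)))
    info <- attr(dat, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8L) {
      stop_io("unsupported format: '%s' has bit depth %d (> 8)", path, info$bit.depth)
    }
  } else if (ext %in% c("tif", "tiff")) {
    dat <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) stop_io("cannot read TIFF '%s': %s", path, conditionMessage(e)))
    bps <- attr(dat, "bits.per.sample")
    if (!is.null(bps) && any(bps > 8L)) {
      stop_io("unsupported format: '%s' has bit depth %d (> 8)", path, max(bps))
    }
  } else {
    stop_io("unsupported format '%s' (expected PNG or TIFF): '%s'", ext, path)
  }
  px <- channels_to_luminance(dat)
  gray_image(round_half_away(px * 255))
}

channels_to_luminance <- function(dat) {
  d <- dim(dat)
  if (length(d) == 2L) {
    out <- unclass(dat)
    attributes(out) <- list(dim = d)
    return(out)
  }
  plane <- function(i) {
    p <- dat[, , i]
    dim(p) <- d[1:2]  # keep 1x1 and 1xN planes as matrices
    p
  }
  if (d[3L] >= 3L) {
    0.299 * plane(1L) + 0.587 * plane(2L) + 0.114 * plane(3L)
  } else {
    plane(1L)  # gray or gray + alpha
  }
}

#' Write an 8-bit grayscale image losslessly
#'
#' PNG uses deflate; TIFF is written with deflate compression. Both are
#' lossless: `read_image(write_image(x, path))` is bit-exact.
#'
#' @param img A [gray_image].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- gray_image(as.matrix(unclass(img)), dpi = attr(img, "dpi"))
  if (!dir.exists(dirname(path))) {
    stop_io("cannot write image: directory '%s' does not exist", dirname(path))
  }
  norm <- as_gray_matrix(img) / 255
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext == "png") {
      png::writePNG(norm, path)
    } else if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(norm, path, bits.per.sample = 8L, compression = "deflate")
    } else {
      stop_io("unsupported output format '%s' (expected PNG or TIFF)", ext)
    }
    TRUE
  }, error = function(e) {
    if (inherits(e, "sbpn_error")) stop(e)
    stop_io("cannot write image to '%s': %s", path, conditionMessage(e))
  })
  invisible(path)
}
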