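#' Single-channel raster image
#'
#' The substrate of every pipeline: one 2D fluorescence channel stored as a
#' numeric matrix (rows = y, columns = x), with the physical pixel size in
#' micrometres per pixel, a channel label, and the acquisition bit depth.
#' Intensities are kept on a normalized continuous scale (nominally
#' \code{[0, 1]} = full bit-depth range); TIFF I/O performs the quantization.
#'
#' @param pixels numeric matrix of non-negative, finite intensities.
#' @param pixel_size_um physical size of one pixel in micrometres (> 0).
#' @param channel character label, e.g. \code{"cd31"}, \code{"dapi"}.
#' @param bit_depth acquisition bit depth, 8 or 16.
#' @return an object of class \code{raster_image}.
#' @examples
#' img <- raster_image(matrix(runif(64), 8, 8), pixel_size_um = 0.31)
#' dim(img$pixels)
#' @export
raster_image <- function(pixels, pixel_size_um = 1, channel = "", bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stopf("image contains non-finite values")
  if (any(pixels < 0))
    stopf("image contains negative intensities")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stopf("'pixel_size_um' must be a single positive number")
  if (!bit_depth %in% c(8L, 16L))
    stopf("'bit_depth' must be 8 or 16, got %s", bit_depth)
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel = as.character(channel), bit_depth = as.integer(bit_depth)),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %dx%d px, %.4g um/px, channel '%s', %d-bit\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel,
              x$bit_depth))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

# Accept either a raster_image or a bare matrix; return the pixel matrix.
as_pixels <- function(image) {
  if (inherits(image, "raster_image")) image$pixels
  else if (is.matrix(image)) image
  else stopf("expected a raster_image or a matrix, got %s", class(image)[1])
}

pixel_size_of <- function(image, default = 1) {
  if (inherits(image, "raster_image")) image$pixel_size_um
  else if (inherits(image, "binary_mask")) attr(image, "pixel_size_um")
  else default
}

#' Binary segmentation mask
#'
#' A logical matrix of the same shape as its source image, carrying the pixel
#' size so downstream area/length measurements stay calibrated.
#'
#' @param pixels logical (or 0/1) matrix.
#' @param pixel_size_um micrometres per pixel.
#' @return an object of class \code{binary_mask} (a logical matrix with
#'   attributes).
#' @export
binary_mask <- function(pixels, pixel_size_um = 1) {
  if (is.matrix(pixels) && !is.logical(pixels)) pixels <- pixels != 0
  if (!is.matrix(pixels) || !is.logical(pixels))
    stopf("'pixels' must be a logical matrix")
  structure(pixels, pixel_size_um = pixel_size_um, class = c("binary_mask", "matrix"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %dx%d px, %.4g um/px, %d foreground px\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), sum(x)))
  invisible(x)
}

# Plain logical matrix from a binary_mask / logical matrix.
as_mask <- function(mask) {
  if (inherits(mask, "binary_mask")) {
    matrix(as.logical(mask), nrow(mask), ncol(mask))
  } else if (is.matrix(mask)) {
    mask != 0
  } else stopf("expected a binary_mask or matrix, got %s", class(mask)[1])
}
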