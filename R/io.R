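# TIFF and table I/O ----------------------------------------------------------

#' Read channels from a TIFF file
#'
#' Accepts single- or multi-page 8/16-bit grayscale TIFF and RGB pages.
#' Channels are addressed by a \code{channel_map} of name to page index
#' (1-based); for an RGB page, an entry \code{c(page, plane)} selects a color
#' plane, and a bare RGB page requested as one channel is reduced by the
#' unweighted mean of its planes. Intensities are returned on the normalized
#' \code{[0, 1]} scale.
#'
#' @param path TIFF file path.
#' @param channel_map named list of page indices (or \code{c(page, plane)}).
#'   \code{NULL} reads all pages as \code{channel1}, \code{channel2}, ...
#' @param pixel_size_um pixel size to stamp on the channels (config overrides
#'   any file metadata, with a warning if both are present).
#' @return named list of \code{\link{raster_image}}s.
#' @export
read_image <- function(path, channel_map = NULL, pixel_size_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- vapply(pages, function(p) {
    b <- attr(p, "bits.per.sample")
    if (is.null(b)) 16L else as.integer(b)
  }, integer(1))
  if (any(!bits %in% c(8L, 16L)))
    stopf("unsupported bit depth %s: only 8- and 16-bit TIFF are handled",
          paste(unique(bits[!bits %in% c(8L, 16L)]), collapse = ", "))
  if (is.null(channel_map)) {
    channel_map <- as.list(seq_along(pages))
    names(channel_map) <- paste0("channel", seq_along(pages))
  }
  out <- list()
  for (nm in names(channel_map)) {
    sel <- channel_map[[nm]]
    page_i <- sel[1]
    if (page_i > length(pages))
      stopf("channel '%s' requests page %d but the file has %d page(s)",
            nm, page_i, length(pages))
    page <- pages[[page_i]]
    maxval <- 2^bits[page_i] - 1
    px <- if (length(dim(page)) == 3) {
      if (length(sel) > 1) page[, , sel[2]] else apply(page, c(1, 2), mean)
    } else page
    out[[nm]] <- raster_image(matrix(px / maxval, nrow(px), ncol(px)),
                              pixel_size_um = pixel_size_um, channel = nm,
                              bit_depth = bits[page_i])
  }
  out
}

#' Write channels to a multi-page 16-bit TIFF
#'
#' Intensities are clipped to \code{[0, 1]} and quantized to 16 bits.
#'
#' @param images named list of \code{\link{raster_image}}s (or matrices).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(images, path) {
  mats <- lapply(images, function(im) pmin(pmax(as_pixels(im), 0), 1))
  tiff::writeTIFF(mats, path, bits.per.sample = 16L)
  invisible(path)
}

#' Save a simulated field (images, truth tables, parameter sidecar)
#'
#' Writes per-channel 16-bit TIFFs, the ground truth as CSV (one row per
#' vessel / nucleus / interface) and a JSON sidecar with the generator
#' parameters and seed.
#'
#' @param sim result of one of the \code{generate_*_image} functions.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param params parameter list recorded in the sidecar.
#' @return the directory, invisibly.
#' @export
save_simulation <- function(sim, dir, prefix = "field", params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chans <- sim[vapply(sim, inherits, logical(1), "raster_image")]
  for (nm in names(chans)) {
    write_image(chans[nm], file.path(dir, sprintf("%s_%s.tif", prefix, nm)))
  }
  truth <- sim$truth
  truth_df <- if (inherits(truth, "vessel_truth")) truth$vessels
              else if (inherits(truth, "junction_truth")) {
                data.frame(interface = seq_along(truth$interfaces),
                           length_px = truth$interface_length_px,
                           gap_count = truth$gap_count_per_interface)
              } else as.data.frame(truth)
  write.csv(truth_df, file.path(dir, sprintf("%s_truth.csv", prefix)),
            row.names = FALSE)
  jsonlite::write_json(params, file.path(dir, sprintf("%s_params.json", prefix)),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load an analysis configuration from YAML
#'
#' Recognized blocks: \code{pixel_size_um}, \code{channels} (name to page
#' index), \code{frangi} (scales_px, alpha, beta, c), \code{particles}
#' (min_size_um2, circularity), \code{hysteresis} (low, high),
#' \code{nuclei} (min_area_px, smooth_sigma_px), \code{noise}, \code{seed}.
#' Missing blocks fall back to package defaults.
#'
#' @param path YAML file path, or \code{NULL} for all defaults.
#' @return a list of class \code{analysis_config}.
#' @export
analysis_config <- function(path = NULL) {
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- list(
    pixel_size_um = user$pixel_size_um %||% 1,
    channels = user$channels %||% list(),
    frangi = do.call(frangi_params, user$frangi %||% list()),
    particles = list(
      min_size_um2 = user$particles$min_size_um2 %||% 10,
      circularity = user$particles$circularity %||% c(0, 1)),
    hysteresis = list(low = user$hysteresis$low, high = user$hysteresis$high),
    nuclei = list(min_area_px = user$nuclei$min_area_px %||% 30,
                  smooth_sigma_px = user$nuclei$smooth_sigma_px %||% 1),
    seed = user$seed %||% 1L
  )
  structure(cfg, class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
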