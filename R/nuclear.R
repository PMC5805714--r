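# DAPI-driven nuclear segmentation and marker quantification ------------------

#' Subtract a rolling-minimum background
#'
#' Morphological opening with a large disc removes structures smaller than
#' the disc, leaving the smooth background, which is then subtracted
#' (clipped at zero).
#'
#' @param image a \code{\link{raster_image}} or matrix.
#' @param radius_px structuring-element radius; should exceed the largest
#'   genuine structure.
#' @return background-subtracted image of the same class.
#' @export
subtract_background <- function(image, radius_px = 25) {
  px <- as_pixels(image)
  size <- 2L * as.integer(radius_px) + 1L
  bg <- EBImage::opening(px, EBImage::makeBrush(size, shape = "disc"))
  out <- pmax(px - bg, 0)
  if (inherits(image, "raster_image")) {
    raster_image(out, image$pixel_size_um, image$channel, image$bit_depth)
  } else out
}

#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing, Otsu thresholding, hole filling, size filtering, and
#' a distance-transform watershed to split touching nuclei. An image with no
#' nuclei yields zero labels (not an error).
#'
#' @param dapi a \code{\link{raster_image}} of the DAPI channel.
#' @param min_area_px minimum nucleus area in pixels.
#' @param smooth_sigma_px Gaussian smoothing sigma.
#' @param watershed_tolerance minimum distance-map depth between two maxima
#'   to split them (EBImage watershed tolerance).
#' @return integer label matrix (0 = background) with attribute
#'   \code{pixel_size_um}.
#' @export
segment_nuclei <- function(dapi, min_area_px = 30, smooth_sigma_px = 1,
                           watershed_tolerance = 1) {
  px <- as_pixels(dapi)
  sm <- if (smooth_sigma_px > 0) {
    r <- max(1L, ceiling(3 * smooth_sigma_px))
    k <- dnorm(seq(-r, r), sd = smooth_sigma_px); k <- k / sum(k)
    pmax(conv_sep(px, k, k), 0)
  } else px
  if (max(sm) == min(sm))
    return(structure(matrix(0L, nrow(px), ncol(px)),
                     pixel_size_um = pixel_size_of(dapi)))
  mask <- as_mask(otsu_threshold(sm))
  # refine to the half-maximum contour: Otsu on a sparse bimodal histogram
  # settles below half-max and inflates nuclei by a boundary ring. The
  # medians of the two Otsu classes estimate the background level and the
  # nuclear plateau robustly; their midpoint is the half-max threshold.
  thr <- (median(sm[mask]) + median(sm[!mask])) / 2
  mask <- sm > thr
  mask <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask))) > 0
  lab0 <- label8(mask)
  if (max(lab0) > 0) {
    areas <- tabulate(lab0[lab0 > 0], nbins = max(lab0))
    mask <- matrix(lab0 %in% which(areas >= min_area_px), nrow(mask), ncol(mask))
  }
  if (!any(mask))
    return(structure(matrix(0L, nrow(px), ncol(px)),
                     pixel_size_um = pixel_size_of(dapi)))
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(ws), nrow(mask), ncol(mask))
  # watershed can carve sub-minimum fragments; refilter and compact labels
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= min_area_px)
    lab[!(lab %in% keep)] <- 0L
    lab[lab > 0] <- match(lab[lab > 0], sort(unique(lab[lab > 0])))
  }
  structure(lab, pixel_size_um = pixel_size_of(dapi))
}

#' Per-nucleus marker quantification
#'
#' For each labeled nucleus, counts marker-stained pixels (above
#' \code{stain_threshold}) inside the nuclear area and reports the
#' stained-to-total nuclear area ratio and the mean marker intensity. The
#' default threshold is Otsu on the marker intensities restricted to nuclear
#' pixels (with a midpoint fallback when those intensities are constant);
#' the marker image is assumed background-subtracted (see
#' \code{\link{subtract_background}}).
#'
#' @param marker a \code{\link{raster_image}} of the marker channel.
#' @param nuclei label matrix from \code{\link{segment_nuclei}}.
#' @param stain_threshold absolute threshold overriding the Otsu default.
#' @return list of class \code{nuclear_result}: \code{nuclei} (data frame:
#'   id, area_px, marker_stained_fraction, marker_mean_intensity),
#'   \code{summary} (n_nuclei, percent stained nuclear area, mean intensity),
#'   \code{stain_threshold}.
#' @export
nuclear_marker_metrics <- function(marker, nuclei, stain_threshold = NULL) {
  px <- as_pixels(marker)
  if (!all(dim(px) == dim(nuclei)))
    stopf("marker image and nucleus labels have different shapes")
  n <- max(nuclei)
  inside <- nuclei > 0
  if (is.null(stain_threshold)) {
    vals <- px[inside]
    stain_threshold <- if (length(vals) < 2 || max(vals) == min(vals)) {
      max(vals, 0) / 2          # constant marker: positive => stained
    } else {
      # Otsu separates stained from unstained nuclear pixels; the midpoint of
      # the two class medians then puts the cut at the half-maximum of the
      # stain, where the stained region's true boundary lies
      cut0 <- attr(otsu_threshold(matrix(vals, 1)), "threshold")
      (median(vals[vals > cut0]) + median(vals[vals <= cut0])) / 2
    }
  }
  rows <- lapply(seq_len(n), function(l) {
    sel <- nuclei == l
    area <- sum(sel)
    vals <- px[sel]
    data.frame(id = l, area_px = area,
               marker_stained_fraction = mean(vals > stain_threshold),
               marker_mean_intensity = mean(vals))
  })
  df <- if (n > 0) do.call(rbind, rows) else
    data.frame(id = integer(0), area_px = integer(0),
               marker_stained_fraction = numeric(0),
               marker_mean_intensity = numeric(0))
  summary <- data.frame(
    n_nuclei = n,
    percent_stained_nuclear_area = if (n > 0)
      100 * sum(df$marker_stained_fraction * df$area_px) / sum(df$area_px)
      else NA_real_,
    mean_marker_intensity = if (n > 0)
      sum(df$marker_mean_intensity * df$area_px) / sum(df$area_px)
      else NA_real_
  )
  structure(list(nuclei = df, summary = summary,
                 stain_threshold = stain_threshold),
            class = "nuclear_result")
}

#' @export
print.nuclear_result <- function(x, ...) {
  cat(sprintf("<nuclear_result> %d nuclei, %.1f%% stained nuclear area\n",
              x$summary$n_nuclei, x$summary$percent_stained_nuclear_area))
  invisible(x)
}

#' Normalize values to the minimum of a reference group
#'
#' Divides every value by the minimum of the reference group, so the
#' reference minimum maps to 1. The operation is scale-invariant and
#' idempotent.
#'
#' @param values numeric vector.
#' @param groups grouping vector (same length).
#' @param reference the reference group label (default: first encountered).
#' @return normalized numeric vector.
#' @export
normalize_to_group_min <- function(values, groups, reference = NULL) {
  if (length(values) != length(groups)) stopf("values and groups differ in length")
  if (is.null(reference)) reference <- groups[1]
  ref_vals <- values[groups == reference]
  if (!length(ref_vals)) stopf("reference group '%s' is empty", reference)
  ref_min <- min(ref_vals)
  if (ref_min <= 0) stopf("reference-group minimum must be positive, got %g", ref_min)
  values / ref_min
}
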