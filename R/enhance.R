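# Contrast, vesselness and thresholding ---------------------------------------

#' Global histogram equalization
#'
#' Cumulative-histogram mapping over 256 bins spanning the full normalized
#' intensity range \code{[0, 1]}. The transform is monotone non-decreasing,
#' so the rank order of distinct pixel values is preserved; a constant image
#' is returned unchanged (its histogram is already flat).
#'
#' @param image a \code{\link{raster_image}} (values on the normalized
#'   \code{[0, 1]} scale) or a bare matrix.
#' @return equalized image of the same class and metadata.
#' @export
equalize_histogram <- function(image) {
  px <- as_pixels(image)
  if (max(px) == min(px)) return(image)
  idx <- pmin(255L, pmax(0L, floor(pmin(px, 1) * 256)))
  cnt <- tabulate(idx + 1L, nbins = 256L)
  cdf <- cumsum(cnt) / length(px)
  out <- matrix(cdf[idx + 1L], nrow(px), ncol(px))
  if (inherits(image, "raster_image")) {
    raster_image(out, image$pixel_size_um, image$channel, image$bit_depth)
  } else out
}

#' Otsu threshold and mask
#'
#' Finds the threshold maximizing the between-class intensity variance over a
#' 256-bin histogram spanning the observed \code{[min, max]} range (so the
#' result is exactly invariant to constant offsets). Class statistics use the
#' exact per-bin pixel sums, not bin centers, which makes the selected
#' partition identical to an exhaustive search over all 256 candidate cuts.
#'
#' @param image a \code{\link{raster_image}} or matrix with at least two
#'   distinct values.
#' @return a \code{\link{binary_mask}} of pixels above the threshold, with
#'   attribute \code{threshold} (the cut value on the intensity scale).
#' @export
otsu_threshold <- function(image) {
  px <- as_pixels(image)
  lo <- min(px); hi <- max(px)
  if (hi == lo) stopf("Otsu threshold undefined for a constant image")
  w <- (hi - lo) / 256
  idx <- pmin(255L, floor((px - lo) / w))     # bin index 0..255
  cnt <- tabulate(idx + 1L, nbins = 256L)
  sums <- numeric(256L)
  agg <- rowsum(as.vector(px), group = as.vector(idx))
  sums[as.integer(rownames(agg)) + 1L] <- agg
  n <- length(px)
  cum_n <- cumsum(cnt); cum_s <- cumsum(sums)
  k <- 1:255                                   # class 0 = bins 0..k-1
  n0 <- cum_n[k]; n1 <- n - n0
  valid <- n0 > 0 & n1 > 0
  mu0 <- cum_s[k] / n0
  mu1 <- (cum_s[256] - cum_s[k]) / n1
  bcv <- ifelse(valid, n0 * n1 * (mu0 - mu1)^2, -Inf)
  k_opt <- which.max(bcv)                      # first maximum on ties
  thr <- lo + k_opt * w
  mask <- matrix(idx >= k_opt, nrow(px), ncol(px))
  out <- binary_mask(mask, pixel_size_of(image))
  attr(out, "threshold") <- thr
  out
}

#' Frangi vesselness filter parameters
#'
#' @param scales_px Gaussian scales (sigma, px) at which the Hessian is
#'   evaluated; increasing, all positive. Defaults cover vessel radii of
#'   roughly 1-6 px.
#' @param alpha,beta sensitivity of the blobness term R_b (the classical 2D
#'   filter uses a single such constant; both names are accepted and `beta`
#'   is the one used).
#' @param c structureness scale, or \code{"auto"} = half the maximum Frobenius
#'   Hessian norm at each scale.
#' @return an object of class \code{frangi_params}.
#' @export
frangi_params <- function(scales_px = c(1, 2, 3, 4), alpha = 0.5, beta = 0.5,
                          c = "auto") {
  if (length(scales_px) == 0) stopf("at least one Frangi scale is required")
  if (any(scales_px <= 0) || is.unsorted(scales_px))
    stopf("Frangi scales must be positive and increasing")
  if (alpha <= 0 || beta <= 0) stopf("alpha and beta must be positive")
  structure(list(scales_px = scales_px, alpha = alpha, beta = beta, c = c),
            class = "frangi_params")
}

#' Hessian-based Frangi vesselness (2D, bright ridges)
#'
#' At each scale sigma the scale-normalized Hessian (Gaussian derivatives,
#' multiplied by sigma^2) is computed; with eigenvalues ordered
#' \eqn{|\lambda_1| \le |\lambda_2|}, the vesselness is 0 where
#' \eqn{\lambda_2 > 0} (bright tubes have a strongly negative principal
#' curvature) and otherwise
#' \deqn{\exp(-R_b^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2)),}
#' with blobness \eqn{R_b = \lambda_1/\lambda_2} and structureness
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}. The response is the maximum
#' over scales and lies in \code{[0, 1]}; it is identically 0 on a constant
#' image.
#'
#' @param image a \code{\link{raster_image}} or matrix.
#' @param params a \code{\link{frangi_params}}.
#' @return vesselness image of the same class and metadata.
#' @export
frangi_vesselness <- function(image, params = frangi_params()) {
  stopifnot(inherits(params, "frangi_params"))
  px <- as_pixels(image)
  best <- matrix(0, nrow(px), ncol(px))
  for (s in params$scales_px) {
    r <- max(2L, ceiling(3 * s))
    x <- seq(-r, r)
    g <- dnorm(x, sd = s); g <- g / sum(g)
    gxx <- g * (x^2 - s^2) / s^4
    gxx <- gxx - mean(gxx)   # zero DC response of the truncated kernel
    gx <- -g * x / s^2
    hxx <- s^2 * conv_sep(px, g, gxx)
    hyy <- s^2 * conv_sep(px, gxx, g)
    hxy <- s^2 * conv_sep(px, gx, gx)
    tr <- hxx + hyy
    disc <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    e1 <- (tr + disc) / 2
    e2 <- (tr - disc) / 2
    swap <- abs(e1) > abs(e2)
    lam1 <- ifelse(swap, e2, e1)   # |lam1| <= |lam2|
    lam2 <- ifelse(swap, e1, e2)
    S2 <- lam1^2 + lam2^2
    # a flat image has only rounding-level curvature; treat it as zero
    if (max(S2) < 1e-18 * max(1, max(px))^2) next
    cpar <- if (identical(params$c, "auto")) sqrt(max(S2)) / 2 else params$c
    v <- matrix(0, nrow(px), ncol(px))
    ok <- lam2 < 0
    if (cpar > 0 && any(ok)) {
      rb2 <- (lam1[ok] / lam2[ok])^2
      v[ok] <- exp(-rb2 / (2 * params$beta^2)) *
        (1 - exp(-S2[ok] / (2 * cpar^2)))
    }
    best <- pmax(best, v)
  }
  if (inherits(image, "raster_image")) {
    raster_image(best, image$pixel_size_um,
                 paste0(image$channel, ".vesselness"), image$bit_depth)
  } else best
}

#' Hysteresis thresholding
#'
#' Keeps pixels at or above \code{high}, plus pixels at or above \code{low}
#' that are 8-connected to a high pixel through pixels at or above
#' \code{low}. The result therefore always contains the simple high-threshold
#' mask and is contained in the low-threshold mask.
#'
#' @param image a \code{\link{raster_image}} or matrix.
#' @param low,high thresholds with \code{0 <= low <= high}.
#' @return a \code{\link{binary_mask}}.
#' @export
hysteresis_threshold <- function(image, low, high) {
  if (low > high) stopf("hysteresis thresholds must satisfy low <= high")
  if (low < 0) stopf("thresholds must be non-negative")
  px <- as_pixels(image)
  weak <- px >= low
  strong <- px >= high
  if (!any(strong))
    return(binary_mask(matrix(FALSE, nrow(px), ncol(px)), pixel_size_of(image)))
  lab <- label8(weak)
  keep <- sort(unique(lab[strong]))
  keep <- keep[keep > 0]
  binary_mask(matrix(lab %in% keep, nrow(px), ncol(px)), pixel_size_of(image))
}
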