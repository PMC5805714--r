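# Synthetic nuclei fields -----------------------------------------------------
#
# Nuclei are non-overlapping ellipses. The marker-positive region inside a
# nucleus is the concentric sub-ellipse u <= f of the normalized squared
# radius u = (x'/a)^2 + (y'/b)^2, whose area is exactly the fraction f of the
# nucleus area - so the requested marker fraction is the analytic truth, not
# an approximation.

#' Generate a DAPI + marker nucleus field with ground truth
#'
#' Places \code{n_nuclei} non-overlapping ellipses (bounded retries; an error
#' names the constraint if placement fails), renders full ellipses into the
#' DAPI channel and, inside each, a concentric region occupying exactly the
#' requested area fraction into the marker channel.
#'
#' @param shape_px image shape \code{c(nrow, ncol)}.
#' @param n_nuclei number of nuclei.
#' @param axes_range_px range of ellipse semi-axes in px.
#' @param marker_fractions per-nucleus marker area fraction in \code{[0, 1]};
#'   a scalar recycles, \code{NULL} draws uniform(0.2, 0.8).
#' @param marker_intensity per-nucleus mean marker intensity (a.u.).
#' @param noise a \code{\link{noise_model}}.
#' @param pixel_size_um micrometres per pixel.
#' @return list with \code{dapi}, \code{marker} (\code{raster_image}) and
#'   \code{truth} (class \code{nuclei_truth}: data frame of centers, axes,
#'   orientation, marker fraction and intensity).
#' @examples
#' f <- generate_nuclei_image(c(96, 96), n_nuclei = 4, noise = noise_none(3))
#' f$truth
#' @export
generate_nuclei_image <- function(shape_px = c(128L, 128L), n_nuclei = 10,
                                  axes_range_px = c(5, 9),
                                  marker_fractions = NULL,
                                  marker_intensity = 1,
                                  noise = noise_model(),
                                  pixel_size_um = 1) {
  if (!is.null(marker_fractions) &&
      (any(marker_fractions < 0) || any(marker_fractions > 1)))
    stopf("marker_fractions must lie in [0, 1]")
  nr <- shape_px[1]; nc <- shape_px[2]
  res <- with_local_seed(noise$seed, {
    amax <- axes_range_px[2]
    centers <- matrix(numeric(0), 0, 2)
    axes <- matrix(numeric(0), 0, 2)
    theta <- numeric(0)
    tries <- 0L
    while (nrow(centers) < n_nuclei) {
      tries <- tries + 1L
      if (tries > 300L * n_nuclei)
        stopf(paste("could not place %d non-overlapping nuclei with semi-axes",
                    "up to %.1f px in a %dx%d field"),
              n_nuclei, amax, nr, nc)
      a <- runif(1, axes_range_px[1], axes_range_px[2])
      b <- runif(1, axes_range_px[1], min(a, axes_range_px[2]))
      cx <- runif(1, a + 2, nc - 1 - a - 2)
      cy <- runif(1, a + 2, nr - 1 - a - 2)
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(d < axes[, 1] + a + 2)) next
      }
      centers <- rbind(centers, c(cx, cy))
      axes <- rbind(axes, c(a, b))
      theta <- c(theta, runif(1, 0, pi))
    }
    mf <- if (is.null(marker_fractions)) runif(n_nuclei, 0.2, 0.8)
          else rep_len(marker_fractions, n_nuclei)
    mi <- rep_len(marker_intensity, n_nuclei)
    list(centers = centers, axes = axes, theta = theta, mf = mf, mi = mi)
  })
  dapi <- matrix(0, nr, nc)
  marker <- matrix(0, nr, nc)
  for (i in seq_len(n_nuclei)) {
    cx <- res$centers[i, 1]; cy <- res$centers[i, 2]
    a <- res$axes[i, 1]; b <- res$axes[i, 2]; th <- res$theta[i]
    x0 <- max(0L, floor(cx - a - 2)); x1 <- min(nc - 1L, ceiling(cx + a + 2))
    y0 <- max(0L, floor(cy - a - 2)); y1 <- min(nr - 1L, ceiling(cy + a + 2))
    xs <- x0:x1; ys <- y0:y1
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
    Y <- matrix(ys, length(ys), length(xs)) - cy
    xr <- X * cos(th) + Y * sin(th)
    yr <- -X * sin(th) + Y * cos(th)
    u <- (xr / a)^2 + (yr / b)^2
    edge <- min(a, b)
    dval <- (sqrt(u) - 1) * edge
    dapi[ys + 1L, xs + 1L] <- pmax(dapi[ys + 1L, xs + 1L],
                                   pmin(pmax(0.5 - dval, 0), 1))
    f <- res$mf[i]
    if (f > 0) {
      dm <- (sqrt(u) - sqrt(f)) * edge
      mval <- pmin(pmax(0.5 - dm, 0), 1) * res$mi[i]
      marker[ys + 1L, xs + 1L] <- pmax(marker[ys + 1L, xs + 1L], mval)
    }
  }
  truth <- structure(
    data.frame(id = seq_len(n_nuclei),
               cx = res$centers[, 1], cy = res$centers[, 2],
               a = res$axes[, 1], b = res$axes[, 2], theta = res$theta,
               marker_fraction = res$mf, marker_intensity = res$mi),
    class = c("nuclei_truth", "data.frame")
  )
  seeds <- with_local_seed(noise$seed, sample.int(2147483646L, 3L))
  n1 <- noise; n1$seed <- seeds[2]
  n2 <- noise; n2$seed <- seeds[3]
  list(
    dapi = apply_noise(raster_image(dapi, pixel_size_um, "dapi"), n1),
    marker = apply_noise(raster_image(marker, pixel_size_um, "marker"), n2),
    truth = truth
  )
}
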