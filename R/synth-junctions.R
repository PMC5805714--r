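# Synthetic endothelial junction fields ---------------------------------------
#
# A confluent monolayer is emulated as a jittered grid of cells whose shared
# borders (interfaces) are polylines. The endothelial compartment channel
# (cd31) stains a band along every interface; the VEC channel stains only the
# recorded runs, leaving gaps of controllable length. Stained runs are
# rendered flat-ended (clipped by arc-length projection, no end caps) so run
# lengths in the image match the recorded intervals.

# Rasterize arc-length intervals of a polyline as a flat-ended band.
rasterize_runs <- function(shape_px, polyline, intervals, radius) {
  nr <- shape_px[1]; nc <- shape_px[2]
  canvas <- matrix(0, nr, nc)
  if (is.null(intervals) || nrow(intervals) == 0) return(canvas)
  seglen <- sqrt(rowSums(diff(polyline)^2))
  cum <- c(0, cumsum(seglen))
  for (k in seq_len(nrow(intervals))) {
    s0 <- intervals[k, 1]; s1 <- intervals[k, 2]
    for (s in seq_len(nrow(polyline) - 1L)) {
      if (seglen[s] == 0) next
      lo <- max(s0, cum[s]); hi <- min(s1, cum[s + 1L])
      if (hi <= lo) next
      t0 <- (lo - cum[s]) / seglen[s]; t1 <- (hi - cum[s]) / seglen[s]
      a <- polyline[s, ] + t0 * (polyline[s + 1L, ] - polyline[s, ])
      b <- polyline[s, ] + t1 * (polyline[s + 1L, ] - polyline[s, ])
      len2 <- sum((b - a)^2)
      if (len2 == 0) next
      rmax <- radius + 1.5
      x0 <- max(0L, floor(min(a[1], b[1]) - rmax))
      x1 <- min(nc - 1L, ceiling(max(a[1], b[1]) + rmax))
      y0 <- max(0L, floor(min(a[2], b[2]) - rmax))
      y1 <- min(nr - 1L, ceiling(max(a[2], b[2]) + rmax))
      if (x1 < x0 || y1 < y0) next
      xs <- x0:x1; ys <- y0:y1
      X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
      Y <- matrix(ys, length(ys), length(xs))
      t <- ((X - a[1]) * (b[1] - a[1]) + (Y - a[2]) * (b[2] - a[2])) / len2
      tc <- pmin(pmax(t, 0), 1)
      dx <- X - (a[1] + tc * (b[1] - a[1]))
      dy <- Y - (a[2] + tc * (b[2] - a[2]))
      d_perp <- sqrt(dx^2 + dy^2)
      seg_l <- sqrt(len2)
      # flat ends only at the true run boundaries; interior polyline joints
      # are continued (round-capped) by the adjacent piece
      axial_out <- 0
      if (abs(lo - s0) < 1e-9) axial_out <- pmax(axial_out, -t * seg_l)
      if (abs(hi - s1) < 1e-9) axial_out <- pmax(axial_out, (t - 1) * seg_l)
      signed <- pmax(d_perp - radius, axial_out)
      val <- pmin(pmax(0.5 - signed, 0), 1)
      block <- canvas[ys + 1L, xs + 1L, drop = FALSE]
      canvas[ys + 1L, xs + 1L] <- pmax(block, val)
    }
  }
  canvas
}

#' Generate a synthetic junction field with ground truth
#'
#' Cell-cell interfaces form a jittered rectangular grid. Along each
#' interface, stained runs alternate with unstained gaps of exactly
#' \code{gap_length_px}; the number of gaps is chosen so the stained
#' fraction is as close as achievable to \code{stained_coverage}. The exact
#' intervals and gap counts are recorded as truth.
#'
#' @param shape_px image shape \code{c(nrow, ncol)}.
#' @param n_cells approximate number of cells (grid of
#'   \code{ceiling(sqrt(n_cells))^2} tiles).
#' @param stained_coverage fraction of each interface stained, in
#'   \code{[0, 1]}; 1 means a single continuous run (no gaps).
#' @param gap_length_px target unstained gap length in px.
#' @param noise a \code{\link{noise_model}}.
#' @param pixel_size_um micrometres per pixel.
#' @param band_radius_px half-width of the endothelial compartment band.
#' @param vec_radius_px half-width of the VEC stain band.
#' @return list with \code{cd31}, \code{vec} (\code{raster_image}) and
#'   \code{truth} (class \code{junction_truth}: per-interface polylines,
#'   stained run intervals, lengths, gap counts, plus totals).
#' @examples
#' f <- generate_junction_image(c(96, 96), n_cells = 4,
#'                              stained_coverage = 0.6,
#'                              noise = noise_none(5))
#' f$truth$gap_count
#' @export
generate_junction_image <- function(shape_px = c(128L, 128L), n_cells = 9,
                                    stained_coverage = 0.7,
                                    gap_length_px = 8,
                                    noise = noise_model(),
                                    pixel_size_um = 1,
                                    band_radius_px = 3,
                                    vec_radius_px = 1.5) {
  if (stained_coverage < 0 || stained_coverage > 1)
    stopf("stained_coverage must lie in [0, 1]")
  nr <- shape_px[1]; nc <- shape_px[2]
  k <- ceiling(sqrt(n_cells))
  margin <- 6
  res <- with_local_seed(noise$seed, {
    # (k+1) x (k+1) grid of nodes, interior nodes jittered
    gx <- seq(margin, nc - 1 - margin, length.out = k + 1)
    gy <- seq(margin, nr - 1 - margin, length.out = k + 1)
    jit <- 0.18 * min(diff(gx)[1], diff(gy)[1])
    nodes <- array(0, dim = c(k + 1, k + 1, 2))
    for (i in seq_len(k + 1)) for (j in seq_len(k + 1)) {
      dx <- if (i %in% c(1, k + 1) || j %in% c(1, k + 1)) 0 else runif(1, -jit, jit)
      dy <- if (i %in% c(1, k + 1) || j %in% c(1, k + 1)) 0 else runif(1, -jit, jit)
      nodes[i, j, ] <- c(gx[i] + dx, gy[j] + dy)
    }
    interfaces <- list()
    add_iface <- function(p1, p2) {
      mid <- (p1 + p2) / 2 + runif(2, -jit / 2, jit / 2)
      pl <- rbind(p1, mid, p2)
      interfaces[[length(interfaces) + 1L]] <<- pl
    }
    for (i in seq_len(k + 1)) for (j in seq_len(k)) {
      add_iface(nodes[i, j, ], nodes[i, j + 1, ])       # vertical edges
    }
    for (i in seq_len(k)) for (j in seq_len(k + 1)) {
      add_iface(nodes[i, j, ], nodes[i + 1, j, ])       # horizontal edges
    }
    # stained run layout per interface
    runs <- vector("list", length(interfaces))
    gaps <- integer(length(interfaces))
    for (e in seq_along(interfaces)) {
      L <- polyline_length(interfaces[[e]])
      cv <- stained_coverage
      if (cv >= 1) {
        runs[[e]] <- matrix(c(0, L), 1, 2); gaps[e] <- 0L
      } else if (cv <= 0) {
        runs[[e]] <- matrix(numeric(0), 0, 2); gaps[e] <- 0L
      } else {
        # gaps have exactly the requested length; the coverage sets how many
        # fit, so the realized coverage is the closest achievable to `cv`
        ngap <- round((1 - cv) * L / gap_length_px)
        while (ngap > 0 && L - ngap * gap_length_px < (ngap + 1) * 1)
          ngap <- ngap - 1L   # keep every run at least 1 px long
        if (ngap == 0L) {
          runs[[e]] <- matrix(c(0, L), 1, 2); gaps[e] <- 0L
        } else {
          glen <- gap_length_px
          rlen <- (L - ngap * glen) / (ngap + 1L)
          s <- 0
          rr <- matrix(0, ngap + 1L, 2)
          for (q in seq_len(ngap + 1L)) {
            rr[q, ] <- c(s, s + rlen)
            s <- s + rlen + glen
          }
          rr[ngap + 1L, 2] <- L  # absorb rounding
          runs[[e]] <- rr
          gaps[e] <- ngap
        }
      }
    }
    list(interfaces = interfaces, runs = runs, gaps = gaps)
  })
  cd31 <- matrix(0, nr, nc)
  vec <- matrix(0, nr, nc)
  lens <- numeric(length(res$interfaces))
  for (e in seq_along(res$interfaces)) {
    pl <- res$interfaces[[e]]
    lens[e] <- polyline_length(pl)
    cd31 <- pmax(cd31, rasterize_tubes(shape_px, list(pl), list(band_radius_px)))
    vec <- pmax(vec, rasterize_runs(shape_px, pl, res$runs[[e]], vec_radius_px))
  }
  truth <- structure(
    list(interfaces = res$interfaces, stained_runs = res$runs,
         interface_length_px = lens, gap_count_per_interface = res$gaps,
         gap_count = sum(res$gaps),
         stained_length_px = sum(vapply(res$runs, function(r)
           if (nrow(r)) sum(r[, 2] - r[, 1]) else 0, numeric(1))),
         shape_px = shape_px, pixel_size_um = pixel_size_um),
    class = "junction_truth"
  )
  seeds <- with_local_seed(noise$seed, sample.int(2147483646L, 5L))
  n1 <- noise; n1$seed <- seeds[4]
  n2 <- noise; n2$seed <- seeds[5]
  list(
    cd31 = apply_noise(raster_image(cd31, pixel_size_um, "cd31"), n1),
    vec = apply_noise(raster_image(vec, pixel_size_um, "vec"), n2),
    truth = truth
  )
}

#' @export
print.junction_truth <- function(x, ...) {
  cat(sprintf("<junction_truth> %d interfaces, stained %.1f px of %.1f px, %d gaps\n",
              length(x$interfaces), x$stained_length_px,
              sum(x$interface_length_px), x$gap_count))
  invisible(x)
}
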