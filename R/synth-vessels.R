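# Synthetic vessel fields -----------------------------------------------------
#
# Vessels are rendered as anti-aliased capsules around sub-pixel polylines:
# intensity 1 in the core, a 1-px linear soft edge, and the half-maximum
# contour exactly at the stated radius. That places the Otsu boundary of a
# noise-free rendering at the true radius, which is what makes diameter
# recovery testable against ground truth.

polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Rasterize tubes (capsules) around polylines
#'
#' @param shape_px image shape \code{c(nrow, ncol)}.
#' @param polylines list of n x 2 matrices (columns x, y; 0-based, sub-pixel).
#' @param radii list of per-point radius vectors (px), matched to
#'   \code{polylines}; a scalar per polyline is recycled.
#' @return numeric matrix in \code{[0, 1]}.
#' @keywords internal
rasterize_tubes <- function(shape_px, polylines, radii) {
  nr <- shape_px[1]; nc <- shape_px[2]
  canvas <- matrix(0, nr, nc)
  for (i in seq_along(polylines)) {
    p <- polylines[[i]]
    r <- radii[[i]]
    if (length(r) == 1L) r <- rep(r, nrow(p))
    if (any(r <= 0)) stopf("tube radii must be positive")
    if (nrow(p) < 2 || polyline_length(p) <= 0)
      stopf("degenerate geometry: zero-length polyline (vessel %d)", i)
    for (s in seq_len(nrow(p) - 1L)) {
      a <- p[s, ]; b <- p[s + 1L, ]
      ra <- r[s]; rb <- r[s + 1L]
      len2 <- sum((b - a)^2)
      if (len2 == 0) next
      rmax <- max(ra, rb) + 1.5
      x0 <- max(0L, floor(min(a[1], b[1]) - rmax))
      x1 <- min(nc - 1L, ceiling(max(a[1], b[1]) + rmax))
      y0 <- max(0L, floor(min(a[2], b[2]) - rmax))
      y1 <- min(nr - 1L, ceiling(max(a[2], b[2]) + rmax))
      if (x1 < x0 || y1 < y0) next
      xs <- x0:x1; ys <- y0:y1
      X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
      Y <- matrix(ys, length(ys), length(xs))
      t <- ((X - a[1]) * (b[1] - a[1]) + (Y - a[2]) * (b[2] - a[2])) / len2
      t <- pmin(pmax(t, 0), 1)
      dx <- X - (a[1] + t * (b[1] - a[1]))
      dy <- Y - (a[2] + t * (b[2] - a[2]))
      d <- sqrt(dx^2 + dy^2)
      rl <- ra + t * (rb - ra)
      val <- pmin(pmax(0.5 - (d - rl), 0), 1)
      block <- canvas[ys + 1L, xs + 1L, drop = FALSE]
      canvas[ys + 1L, xs + 1L] <- pmax(block, val)
    }
  }
  canvas
}

#' Ground truth for a synthetic vessel field
#'
#' @param centerlines list (one element per vessel) of lists of polylines
#'   (n x 2 matrices, columns x and y in px). A branched vessel holds its
#'   parent and child polylines.
#' @param radii matching nested list of per-point radii (px); scalars recycle.
#' @param perfused logical, one flag per vessel.
#' @param shape_px image shape \code{c(nrow, ncol)}.
#' @param branch_points optional matrix with columns x, y, vessel.
#' @param pixel_size_um micrometres per pixel.
#' @return an object of class \code{vessel_truth} with per-vessel summaries
#'   (\code{$vessels}: id, perfused, mean radius, length, branch count) and
#'   \code{$total_length_px}.
#' @export
vessel_truth <- function(centerlines, radii, perfused, shape_px,
                         branch_points = NULL, pixel_size_um = 1) {
  n <- length(centerlines)
  stopifnot(length(radii) == n, length(perfused) == n)
  if (is.null(branch_points))
    branch_points <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "vessel")))
  lens <- numeric(n); mrad <- numeric(n); nbr <- integer(n)
  for (i in seq_len(n)) {
    pls <- centerlines[[i]]
    rr <- radii[[i]]
    for (j in seq_along(pls)) {
      if (length(rr[[j]]) == 1L) rr[[j]] <- rep(rr[[j]], nrow(pls[[j]]))
      if (any(rr[[j]] <= 0)) stopf("radii must be positive (vessel %d)", i)
      lens[i] <- lens[i] + polyline_length(pls[[j]])
    }
    radii[[i]] <- rr
    mrad[i] <- mean(unlist(rr))
    nbr[i] <- sum(nrow(branch_points) > 0 & branch_points[, "vessel"] == i)
  }
  structure(
    list(
      vessels = data.frame(id = seq_len(n), perfused = as.logical(perfused),
                           mean_radius_px = mrad, length_px = lens,
                           n_branches = nbr),
      centerlines = centerlines, radii = radii,
      branch_points = branch_points,
      total_length_px = sum(lens),
      shape_px = shape_px, pixel_size_um = pixel_size_um
    ),
    class = "vessel_truth"
  )
}

#' @export
print.vessel_truth <- function(x, ...) {
  cat(sprintf("<vessel_truth> %d vessels, total length %.1f px, %d branch points\n",
              nrow(x$vessels), x$total_length_px, nrow(x$branch_points)))
  invisible(x)
}

#' Render CD31 / lectin channels from a vessel truth
#'
#' @param truth a \code{\link{vessel_truth}}.
#' @param noise a \code{\link{noise_model}} applied to both channels (with
#'   decorrelated per-channel sub-seeds).
#' @param intensity peak tube intensity before noise.
#' @return list with \code{cd31} and \code{lectin} \code{raster_image}s.
#' @export
render_vessels <- function(truth, noise = noise_none(), intensity = 1) {
  all_pl <- list(); all_r <- list(); perf_pl <- list(); perf_r <- list()
  for (i in seq_len(nrow(truth$vessels))) {
    for (j in seq_along(truth$centerlines[[i]])) {
      all_pl[[length(all_pl) + 1L]] <- truth$centerlines[[i]][[j]]
      all_r[[length(all_r) + 1L]] <- truth$radii[[i]][[j]]
      if (truth$vessels$perfused[i]) {
        perf_pl[[length(perf_pl) + 1L]] <- truth$centerlines[[i]][[j]]
        perf_r[[length(perf_r) + 1L]] <- truth$radii[[i]][[j]]
      }
    }
  }
  cd31 <- rasterize_tubes(truth$shape_px, all_pl, all_r) * intensity
  lectin <- if (length(perf_pl)) {
    rasterize_tubes(truth$shape_px, perf_pl, perf_r) * intensity
  } else matrix(0, truth$shape_px[1], truth$shape_px[2])
  seeds <- with_local_seed(noise$seed, sample.int(2147483646L, 2L))
  n1 <- noise; n1$seed <- seeds[1]
  n2 <- noise; n2$seed <- seeds[2]
  list(
    cd31 = apply_noise(raster_image(cd31, truth$pixel_size_um, "cd31"), n1),
    lectin = apply_noise(raster_image(lectin, truth$pixel_size_um, "lectin"), n2)
  )
}

# One bounded-curvature random walk from a random image edge inward.
# Returns an n x 2 polyline (x, y) or NULL if too short.
random_centerline <- function(shape_px, step = 2, max_turn = 0.18,
                              min_len = NULL, max_len = Inf, margin = 0) {
  nr <- shape_px[1]; nc <- shape_px[2]
  if (is.null(min_len)) min_len <- 0.5 * min(nr, nc)
  side <- sample.int(4L, 1L)
  if (side == 1L) { start <- c(margin, runif(1, 0, nr - 1)); heading <- 0 }
  else if (side == 2L) { start <- c(nc - 1 - margin, runif(1, 0, nr - 1)); heading <- pi }
  else if (side == 3L) { start <- c(runif(1, 0, nc - 1), margin); heading <- pi / 2 }
  else { start <- c(runif(1, 0, nc - 1), nr - 1 - margin); heading <- -pi / 2 }
  heading <- heading + runif(1, -0.5, 0.5)
  pts <- matrix(start, 1, 2)
  cur <- start
  for (k in seq_len(ceiling(2.5 * (nr + nc) / step))) {
    heading <- heading + runif(1, -max_turn, max_turn)
    nxt <- cur + step * c(cos(heading), sin(heading))
    inside <- nxt[1] >= 0 && nxt[1] <= nc - 1 && nxt[2] >= 0 && nxt[2] <= nr - 1
    if (!inside) {
      # clip the final step at the image border
      lo <- 0; hi <- 1
      for (it in 1:20) {
        mid <- (lo + hi) / 2
        p <- cur + mid * (nxt - cur)
        if (p[1] >= 0 && p[1] <= nc - 1 && p[2] >= 0 && p[2] <= nr - 1) lo <- mid else hi <- mid
      }
      pts <- rbind(pts, cur + lo * (nxt - cur))
      break
    }
    pts <- rbind(pts, nxt)
    cur <- nxt
    if ((nrow(pts) - 1L) * step >= max_len) break
  }
  if (polyline_length(pts) < min_len) NULL else pts
}

# Tangent direction of a polyline at arc-length fraction u.
polyline_point_tangent <- function(p, u) {
  seglen <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seglen))
  target <- u * cum[length(cum)]
  s <- max(1L, findInterval(target, cum, rightmost.closed = TRUE))
  s <- min(s, nrow(p) - 1L)
  t <- (target - cum[s]) / seglen[s]
  pt <- p[s, ] + t * (p[s + 1L, ] - p[s, ])
  tang <- atan2(p[s + 1L, 2] - p[s, 2], p[s + 1L, 1] - p[s, 1])
  list(point = pt, tangent = tang, index = s)
}

# Minimum distance from each point of `pts` to polyline `pl`.
points_to_polyline_dist <- function(pts, pl) {
  d <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(pl) - 1L)) {
    a <- pl[s, ]; b <- pl[s + 1L, ]
    len2 <- sum((b - a)^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * (b[1] - a[1]) + (pts[, 2] - a[2]) * (b[2] - a[2])) / len2
    t <- pmin(pmax(t, 0), 1)
    dd <- sqrt((pts[, 1] - (a[1] + t * (b[1] - a[1])))^2 +
               (pts[, 2] - (a[2] + t * (b[2] - a[2])))^2)
    d <- pmin(d, dd)
  }
  d
}

# A child branch is acceptable when, past the junction zone (arc length
# 3 * radius from its origin), it keeps at least a tube diameter of clearance
# from the parent centerline - otherwise the two tubes fuse into one blob.
branch_clear_of_parent <- function(child, parent, radius) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(child)^2))))
  far <- child[arc > 3 * radius, , drop = FALSE]
  if (nrow(far) == 0) return(FALSE)
  all(points_to_polyline_dist(far, parent) > 2 * radius + 1.5)
}

# Random walk for a child branch starting at `start` with heading `heading`.
branch_centerline <- function(shape_px, start, heading, step = 2,
                              max_turn = 0.18, max_len = Inf) {
  nr <- shape_px[1]; nc <- shape_px[2]
  pts <- matrix(start, 1, 2)
  cur <- start; total <- 0
  repeat {
    heading <- heading + runif(1, -max_turn, max_turn)
    nxt <- cur + step * c(cos(heading), sin(heading))
    if (nxt[1] < 0 || nxt[1] > nc - 1 || nxt[2] < 0 || nxt[2] > nr - 1) break
    pts <- rbind(pts, nxt)
    total <- total + step
    cur <- nxt
    if (total >= max_len) break
  }
  pts
}

#' Generate a synthetic multi-channel vessel field with ground truth
#'
#' Draws curvilinear vessels as bounded-curvature random walks (optionally
#' with one child branch each), rasterizes them as anti-aliased tubes of the
#' stated radii into a CD31 channel, renders the perfused subset into a
#' lectin channel, and returns exact ground truth (centerlines, radii,
#' branch points, perfused flags).
#'
#' Vessels are mutually non-overlapping (placement is retried against an
#' occupancy mask), so every rendered structure maps to exactly one truth
#' vessel.
#'
#' @param shape_px image shape \code{c(nrow, ncol)}, at least 64 x 64.
#' @param n_vessels number of vessels to place.
#' @param radius_range_px min/max tube radius in px; must lie in
#'   \code{(0, min(shape)/8)}.
#' @param branching_prob per-vessel probability of carrying one child branch.
#' @param perfused_fraction fraction of vessels flagged perfused (the lectin
#'   channel renders exactly \code{round(fraction * n)} of them).
#' @param noise a \code{\link{noise_model}}; its seed drives all randomness.
#' @param pixel_size_um micrometres per pixel.
#' @return list with \code{cd31}, \code{lectin} (\code{raster_image}) and
#'   \code{truth} (\code{\link{vessel_truth}}).
#' @examples
#' f <- generate_vessel_image(c(96, 96), n_vessels = 2,
#'                            noise = noise_none(seed = 7))
#' f$truth$vessels
#' @export
generate_vessel_image <- function(shape_px = c(128L, 128L), n_vessels = 4,
                                  radius_range_px = c(3, 5),
                                  branching_prob = 0.25,
                                  perfused_fraction = 0.7,
                                  noise = noise_model(),
                                  pixel_size_um = 1) {
  if (min(shape_px) < 64) stopf("shape must be at least 64x64")
  if (radius_range_px[1] <= 0 || radius_range_px[2] >= min(shape_px) / 8)
    stopf("radius_range_px must lie within (0, min(shape)/8)")
  truth <- with_local_seed(noise$seed, {
    occupancy <- matrix(FALSE, shape_px[1], shape_px[2])
    centerlines <- list(); radii <- list(); bps <- NULL
    placed <- 0L; tries <- 0L
    while (placed < n_vessels) {
      tries <- tries + 1L
      if (tries > 500L * n_vessels)
        stopf("could not place %d non-overlapping vessels in a %dx%d field",
              n_vessels, shape_px[1], shape_px[2])
      r <- runif(1, radius_range_px[1], radius_range_px[2])
      # relax the walk length as placement gets crowded: shorter vessels can
      # still be placed between earlier ones
      relax <- max(0.25, 0.85^(tries %/% 60L))
      pl <- random_centerline(shape_px, min_len = relax * 0.5 * min(shape_px),
                              max_len = if (relax < 1)
                                relax * 1.2 * min(shape_px) else Inf)
      if (is.null(pl)) next
      pls <- list(pl)
      bp <- NULL
      if (runif(1) < branching_prob) {
        at <- polyline_point_tangent(pl, runif(1, 0.35, 0.65))
        ang <- at$tangent + sample(c(-1, 1), 1) * runif(1, 0.6, 1.0)
        child <- branch_centerline(shape_px, at$point, ang, max_turn = 0.1,
                                   max_len = polyline_length(pl) * runif(1, 0.4, 0.7))
        # the child must leave the junction zone and stay clear of the parent
        # so parent and child remain separable tubes
        if (polyline_length(child) >= 8 * r &&
            branch_clear_of_parent(child, pl, r)) {
          pls[[2]] <- child
          bp <- at$point
        }
      }
      cand <- rasterize_tubes(shape_px, pls, as.list(rep(r + 2, length(pls)))) > 0
      if (any(cand & occupancy)) next
      placed <- placed + 1L
      occupancy <- occupancy | cand
      centerlines[[placed]] <- pls
      radii[[placed]] <- as.list(rep(r, length(pls)))
      if (!is.null(bp))
        bps <- rbind(bps, c(bp, placed))
    }
    n_perf <- round(perfused_fraction * n_vessels)
    perfused <- rep(FALSE, n_vessels)
    if (n_perf > 0) perfused[sample.int(n_vessels, n_perf)] <- TRUE
    if (!is.null(bps)) colnames(bps) <- c("x", "y", "vessel")
    vessel_truth(centerlines, radii, perfused, shape_px,
                 branch_points = bps, pixel_size_um = pixel_size_um)
  })
  imgs <- render_vessels(truth, noise)
  list(cd31 = imgs$cd31, lectin = imgs$lectin, truth = truth)
}
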