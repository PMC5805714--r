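# End-to-end vessel morphometry -----------------------------------------------

#' Vessel pipeline configuration
#'
#' @param frangi a \code{\link{frangi_params}}.
#' @param min_size_um2 minimum particle/vessel area (calibrated).
#' @param circularity_range circularity filter for particle analysis.
#' @param boundary \code{"intensity"} (default): the vessel mask is the Otsu
#'   mask of the raw intensity restricted to structures detected by the
#'   vesselness mask, keeping the half-maximum lumen boundary;
#'   \code{"vesselness"}: the Otsu mask of the vesselness response itself.
#' @param end_correction extend open skeleton ends to the mask boundary along
#'   the chain direction (thinning retracts tube ends by about one radius).
#' @param prune_spurs remove short terminal twigs before measuring.
#' @param length_method passed to \code{\link{vessel_length}} for per-segment
#'   measurements (\code{"chord"} avoids the staircase bias of step counting).
#' @return a list of class \code{vessel_config}.
#' @export
vessel_config <- function(frangi = frangi_params(), min_size_um2 = 10,
                          circularity_range = c(0, 1),
                          boundary = c("intensity", "vesselness"),
                          end_correction = TRUE, prune_spurs = TRUE,
                          length_method = "chord") {
  structure(list(frangi = frangi, min_size_um2 = min_size_um2,
                 circularity_range = circularity_range,
                 boundary = match.arg(boundary),
                 end_correction = end_correction, prune_spurs = prune_spurs,
                 length_method = length_method),
            class = "vessel_config")
}

# March from a skeleton endpoint along the outgoing chain direction until the
# mask is left; returns the marched distance (px) and whether the march
# stopped at the image border. Thinning retracts the skeleton slightly from a
# tube end: at a border-cut end the retraction is the full marched distance,
# while at an interior end the tube's rounded cap extends one local radius
# past the centerline end, so that radius is subtracted by the caller.
end_extension_px <- function(endpoint, direction, mask, max_px) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) return(list(dist = 0, at_border = FALSE, u = c(0, 0), normal = c(0, 0)))
  u <- direction / nrm
  step <- 0.5
  dist <- 0
  repeat {
    dist <- dist + step
    if (dist > max_px) return(list(dist = max_px, at_border = FALSE, u = u, normal = c(0, 0)))
    p <- endpoint + dist * u
    r <- round(p[2]) + 1; c <- round(p[1]) + 1
    if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask)) {
      normal <- c(if (c < 1) -1 else if (c > ncol(mask)) 1 else 0,
                  if (r < 1) -1 else if (r > nrow(mask)) 1 else 0)
      return(list(dist = dist - step, at_border = TRUE, u = u,
                  normal = normal / sqrt(sum(normal^2))))
    }
    if (!mask[r, c])
      return(list(dist = dist - step, at_border = FALSE, u = u, normal = c(0, 0)))
  }
}

# remove small components and fill holes
clean_mask <- function(mask, min_size_um2, pixel_size_um) {
  m <- as_mask(mask)
  filled <- EBImage::fillHull(matrix(as.numeric(m), nrow(m), ncol(m))) > 0
  lab <- label8(filled)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab)) * pixel_size_um^2
    keep <- which(areas > min_size_um2)
    filled <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  binary_mask(filled, pixel_size_um)
}

#' Quantify vessel morphology in one field of view
#'
#' The full chain: histogram equalization, Frangi vesselness, Otsu
#' segmentation, mask cleanup (hole filling, speck removal), thinning, branch
#' detection, and per-vessel length (skeleton chain rule) and diameter (EDT
#' central values). A vessel is a connected skeleton component; its length
#' sums its segments plus the retraction correction at open ends, its
#' diameter averages the EDT over its skeleton pixels, and its branch count
#' is the number of merged branch points it contains. Particle analysis of
#' the vessel mask supplies the density and mean-area summary.
#'
#' @param image a \code{\link{raster_image}} of the endothelial (CD31)
#'   channel.
#' @param config a \code{\link{vessel_config}}.
#' @return list of class \code{vessel_result}: \code{vessels} (data frame:
#'   id, length_um, mean_diameter_um, n_branches), \code{summary} (count,
#'   density per mm^2, mean area, mean length, mean diameter, branches per
#'   vessel), \code{mask}, \code{skeleton}, \code{params}.
#' @examples
#' f <- generate_vessel_image(c(96, 96), n_vessels = 2, noise = noise_none(11))
#' r <- vessel_pipeline(f$cd31)
#' r$summary
#' @export
vessel_pipeline <- function(image, config = vessel_config()) {
  stopifnot(inherits(image, "raster_image"))
  psz <- image$pixel_size_um
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("vessel_pipeline stage '%s': %s", name, conditionMessage(e)))
  }
  empty <- function() {
    list(vessels = data.frame(id = integer(0), length_um = numeric(0),
                              mean_diameter_um = numeric(0),
                              n_branches = integer(0)),
         summary = data.frame(n_vessels = 0L, density_per_mm2 = 0,
                              mean_area_um2 = NA_real_,
                              mean_length_um = NA_real_,
                              mean_diameter_um = NA_real_,
                              branches_per_vessel = NA_real_),
         mask = binary_mask(matrix(FALSE, nrow(image$pixels), ncol(image$pixels)), psz),
         skeleton = NULL, params = config)
  }
  if (max(image$pixels) == min(image$pixels)) return(structure(empty(), class = "vessel_result"))

  eq <- stage("equalize", equalize_histogram(image))
  ves <- stage("frangi", frangi_vesselness(eq, config$frangi))
  mask_v <- stage("otsu.vesselness", {
    if (max(ves$pixels) == 0) NULL else otsu_threshold(ves)
  })
  if (is.null(mask_v) || !any(mask_v)) return(structure(empty(), class = "vessel_result"))
  mask <- stage("otsu.boundary", {
    if (config$boundary == "intensity") {
      mi <- otsu_threshold(image)
      lab <- label8(as_mask(mi))
      hit <- sort(unique(lab[as_mask(mask_v) & lab > 0]))
      binary_mask(matrix(lab %in% hit, nrow(lab), ncol(lab)), psz)
    } else mask_v
  })
  mask <- stage("cleanup", clean_mask(mask, config$min_size_um2, psz))
  if (!any(mask)) return(structure(empty(), class = "vessel_result"))
  particles <- stage("particles",
    analyze_particles(mask, config$min_size_um2, config$circularity_range))
  skel <- stage("skeletonize", {
    s <- skeletonize(mask)
    if (config$prune_spurs) prune_skeleton(s, mask) else s
  })
  m <- as_mask(mask)
  edt <- EBImage::distmap(matrix(as.numeric(m), nrow(m), ncol(m)))
  lab <- label8(skel$pixels)
  ncomp <- max(lab)
  if (ncomp == 0) return(structure(empty(), class = "vessel_result"))
  nb8 <- count_neighbors8(skel$pixels)

  seg_comp <- vapply(skel$segments, function(sg)
    lab[sg[1, "y"] + 1, sg[1, "x"] + 1], integer(1))
  seg_len <- vapply(skel$segments, vessel_length, numeric(1),
                    pixel_size_um = psz, method = config$length_method)
  bp_comp <- if (nrow(skel$branch_points)) {
    vapply(seq_len(nrow(skel$branch_points)), function(i) {
      r <- pmin(pmax(round(skel$branch_points[i, "y"]) + 1, 1), nrow(lab))
      c <- pmin(pmax(round(skel$branch_points[i, "x"]) + 1, 1), ncol(lab))
      # nearest labeled pixel (centroid may fall between branch pixels)
      win <- lab[max(1, r - 2):min(nrow(lab), r + 2),
                 max(1, c - 2):min(ncol(lab), c + 2)]
      max(win)
    }, integer(1))
  } else integer(0)

  bp_xy <- skel$branch_points
  vessels <- do.call(rbind, lapply(seq_len(ncomp), function(l) {
    ij <- which(lab == l, arr.ind = TRUE)
    len <- 0
    chain_px <- NULL   # trimmed centerline pixels used for the diameter
    for (k in which(seg_comp == l)) {
      sg <- skel$segments[[k]]
      if (!config$end_correction) {
        len <- len + seg_len[k]
        chain_px <- rbind(chain_px, sg)
        next
      }
      n <- nrow(sg)
      free <- if (n >= 2) {
        vapply(c(1L, n), function(endi)
          nb8[sg[endi, "y"] + 1, sg[endi, "x"] + 1] <= 1, logical(1))
      } else c(FALSE, FALSE)
      # inside an end cap the local radius collapses and thinning may leave a
      # short unreliable curl; trim free chain ends whose EDT falls well
      # below the segment's typical radius before measuring and extending
      seg_edt <- edt[cbind(sg[, "y"] + 1, sg[, "x"] + 1)]
      r_typ <- median(seg_edt)
      if (free[1]) {
        while (nrow(sg) > 5 && edt[sg[1, "y"] + 1, sg[1, "x"] + 1] < 0.6 * r_typ)
          sg <- sg[-1, , drop = FALSE]
      }
      if (free[2]) {
        while (nrow(sg) > 5 && edt[sg[nrow(sg), "y"] + 1, sg[nrow(sg), "x"] + 1] < 0.6 * r_typ)
          sg <- sg[-nrow(sg), , drop = FALSE]
      }
      n <- nrow(sg)
      len <- len + vessel_length(sg, psz, method = config$length_method)
      chain_px <- rbind(chain_px, sg)
      if (n < 2) next
      for (side in 1:2) {
        endi <- if (side == 1L) 1L else n
        ep <- sg[endi, ]
        if (!free[side]) {
          # an end attached at a junction: the arm extends to the merged
          # branch point (the junction pixels were removed from the chains)
          if (nrow(bp_xy)) {
            dbp <- sqrt((bp_xy[, "x"] - ep["x"])^2 + (bp_xy[, "y"] - ep["y"])^2)
            if (min(dbp) <= 3) len <- len + min(dbp) * psz
          }
          next
        }
        ref <- sg[if (endi == 1L) min(n, 7L) else max(1L, n - 6L), ]
        dir <- ep - ref
        rloc <- max(edt[ep["y"] + 1, ep["x"] + 1], r_typ)
        mk <- end_extension_px(ep, dir, m, max_px = 2 * rloc + 4)
        # subtract the tube cap that protrudes past the centerline end:
        # the full local radius at interior ends, and at a border exit the
        # in-image part of the cap (shallow, border-parallel exits leave
        # most of the cap inside the field)
        cap <- if (mk$at_border) rloc * (1 - abs(sum(mk$u * mk$normal))) else rloc
        ext <- max(0, mk$dist - cap)
        len <- len + ext * psz
      }
    }
    # the diameter averages the EDT central values along the measured
    # centerline (trimmed chains); untrimmed component pixels in end caps
    # carry collapsed radii and would bias the mean down. Stretches running
    # closer to the image border than their own radius belong to tubes
    # clipped by the field of view, where the EDT reads the visible
    # half-band rather than the vessel; they are excluded when possible.
    diam <- if (!is.null(chain_px) && nrow(chain_px) >= 3) {
      ce <- edt[cbind(chain_px[, "y"] + 1, chain_px[, "x"] + 1)]
      bdist <- pmin(chain_px[, "x"], chain_px[, "y"],
                    ncol(edt) - 1 - chain_px[, "x"],
                    nrow(edt) - 1 - chain_px[, "y"])
      keep <- bdist > ce + 0.5
      if (sum(keep) >= 3) 2 * mean(ce[keep]) * psz else 2 * mean(ce) * psz
    } else 2 * mean(edt[ij]) * psz
    data.frame(id = l, length_um = len, mean_diameter_um = diam,
               n_branches = sum(bp_comp == l))
  }))
  # drop degenerate single-pixel components
  vessels <- vessels[vessels$length_um > 0, , drop = FALSE]
  field_mm2 <- prod(dim(image$pixels)) * (psz / 1000)^2
  summary <- data.frame(
    n_vessels = nrow(vessels),
    density_per_mm2 = nrow(vessels) / field_mm2,
    mean_area_um2 = particles$mean_area_um2,
    mean_length_um = if (nrow(vessels)) mean(vessels$length_um) else NA_real_,
    mean_diameter_um = if (nrow(vessels)) mean(vessels$mean_diameter_um) else NA_real_,
    branches_per_vessel = if (nrow(vessels)) mean(vessels$n_branches) else NA_real_
  )
  structure(list(vessels = vessels, summary = summary, mask = mask,
                 skeleton = skel, particles = particles, params = config),
            class = "vessel_result")
}

#' @export
print.vessel_result <- function(x, ...) {
  cat(sprintf("<vessel_result> %d vessels\n", nrow(x$vessels)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Match pipeline vessels to generator ground truth
#'
#' Assigns each truth vessel the skeleton component found nearest the
#' midpoint of its centerline. Used by verification and acceptance checks.
#'
#' @param result a \code{\link{vessel_pipeline}} result.
#' @param truth a \code{\link{vessel_truth}}.
#' @param search_px half-width of the search window around the centerline
#'   midpoint.
#' @return data frame pairing truth id with recovered vessel id (NA when the
#'   structure was not detected).
#' @export
match_vessels_to_truth <- function(result, truth, search_px = 5) {
  if (is.null(result$skeleton)) {
    return(data.frame(truth_id = truth$vessels$id, vessel_id = NA_integer_))
  }
  lab <- label8(result$skeleton$pixels)
  out <- lapply(seq_len(nrow(truth$vessels)), function(i) {
    pl <- truth$centerlines[[i]][[1]]
    mid <- pl[max(1, round(nrow(pl) / 2)), ]
    r0 <- max(1, round(mid[2]) + 1 - search_px)
    r1 <- min(nrow(lab), round(mid[2]) + 1 + search_px)
    c0 <- max(1, round(mid[1]) + 1 - search_px)
    c1 <- min(ncol(lab), round(mid[1]) + 1 + search_px)
    win <- lab[r0:r1, c0:c1]
    hit <- win[win > 0]
    data.frame(truth_id = i,
               vessel_id = if (length(hit)) as.integer(names(sort(table(hit),
                                  decreasing = TRUE))[1]) else NA_integer_)
  })
  do.call(rbind, out)
}
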