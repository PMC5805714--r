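# VE-cadherin junction metrics ------------------------------------------------

#' Default hysteresis thresholds for VEC staining inside the CD31 compartment
#'
#' \code{high} is the Otsu threshold of the VEC intensities restricted to the
#' CD31 area; \code{low} is half of it.
#' @keywords internal
vec_hysteresis_defaults <- function(vec_px, cd31) {
  vals <- vec_px[cd31]
  if (length(vals) < 2 || max(vals) == min(vals))
    return(list(low = Inf, high = Inf))   # nothing stained
  thr <- attr(otsu_threshold(matrix(vals, 1)), "threshold")
  list(low = 0.5 * thr, high = thr)
}

#' Measure VEC-stained junction lengths inside the CD31 compartment
#'
#' Hysteresis-thresholds the VEC channel (defaults derived from Otsu within
#' the CD31 area), restricts the mask to the CD31 compartment, thins it, and
#' measures the length of each connected VEC run by the skeleton chain rule,
#' with the same end-retraction correction as vessel measurement. Runs are
#' assigned to CD31 structures.
#'
#' @param vec a \code{\link{raster_image}} of the VEC channel.
#' @param cd31_mask \code{\link{binary_mask}} of the vessel / junction
#'   compartment.
#' @param low,high hysteresis thresholds (defaults from Otsu within CD31).
#' @param pixel_size_um micrometres per pixel (defaults to the image's).
#' @return data frame with one row per VEC run: run_id, structure_id,
#'   length_um.
#' @export
junction_length <- function(vec, cd31_mask, low = NULL, high = NULL,
                            pixel_size_um = NULL) {
  px <- as_pixels(vec)
  cm <- as_mask(cd31_mask)
  if (!any(cm)) stopf("empty CD31 mask")
  if (is.null(pixel_size_um)) pixel_size_um <- pixel_size_of(vec)
  if (is.null(low) || is.null(high)) {
    def <- vec_hysteresis_defaults(px, cm)
    if (is.null(low)) low <- def$low
    if (is.null(high)) high <- def$high
  }
  if (!is.finite(high)) {
    return(data.frame(run_id = integer(0), structure_id = integer(0),
                      length_um = numeric(0)))
  }
  vm <- as_mask(hysteresis_threshold(px, low, high)) & cm
  if (!any(vm)) {
    return(data.frame(run_id = integer(0), structure_id = integer(0),
                      length_um = numeric(0)))
  }
  struct_lab <- label8(cm)
  edt <- EBImage::distmap(matrix(as.numeric(vm), nrow(vm), ncol(vm)))
  skel <- skeletonize(binary_mask(vm, pixel_size_um))
  lab <- label8(skel$pixels)
  nb8 <- count_neighbors8(skel$pixels)
  n <- max(lab)
  if (n == 0) {
    return(data.frame(run_id = integer(0), structure_id = integer(0),
                      length_um = numeric(0)))
  }
  rows <- lapply(seq_len(n), function(l) {
    len <- 0
    for (sg in skel$segments) {
      if (lab[sg[1, "y"] + 1, sg[1, "x"] + 1] != l) next
      len <- len + vessel_length(sg, pixel_size_um, method = "chord")
      nn <- nrow(sg)
      if (nn >= 2) {
        for (endi in c(1L, nn)) {
          ep <- sg[endi, ]
          if (nb8[ep["y"] + 1, ep["x"] + 1] > 1) next
          ref <- sg[if (endi == 1L) min(nn, 5L) else max(1L, nn - 4L), ]
          rloc <- edt[ep["y"] + 1, ep["x"] + 1]
          # VEC runs terminate flat at their arc ends (no rounded cap), so
          # the full marched retraction is restored
          mk <- end_extension_px(ep, ep - ref, vm, max_px = 2 * rloc + 3)
          len <- len + mk$dist * pixel_size_um
        }
      }
    }
    ij <- which(lab == l, arr.ind = TRUE)
    sid <- struct_lab[ij[1, 1], ij[1, 2]]
    data.frame(run_id = l, structure_id = sid, length_um = len)
  })
  out <- do.call(rbind, rows)
  out[out$length_um > 0, , drop = FALSE]
}

#' Continuous / discontinuous junction fractions and gap index
#'
#' Stained runs of at least \code{min_run_um} count as continuous junction,
#' shorter runs as discontinuous; the percentages are relative to the total
#' stained length. The gap index is the number of unstained intervals of at
#' least \code{min_gap_um} between consecutive runs, normalized per 100 um of
#' interface. An interface with no runs at all reports missing percentages
#' and one whole-interface gap.
#'
#' @param runs two-column matrix of stained intervals \code{[start, end]} in
#'   micrometres along the interface (disjoint, within its length), or
#'   \code{NULL}/empty for an unstained interface.
#' @param interface_length_um total interface length (> 0).
#' @param min_run_um minimum run length counted as continuous.
#' @param min_gap_um minimum unstained interval counted as a gap.
#' @return list: \code{stained_um}, \code{continuous_percent},
#'   \code{discontinuous_percent}, \code{n_runs}, \code{gap_count},
#'   \code{gap_index} (gaps per 100 um).
#' @export
junction_continuity <- function(runs, interface_length_um, min_run_um = 2,
                                min_gap_um = 0.5) {
  if (interface_length_um <= 0) stopf("interface length must be positive")
  if (is.null(runs) || nrow(runs) == 0) {
    return(list(stained_um = 0, continuous_percent = NA_real_,
                discontinuous_percent = NA_real_, n_runs = 0L,
                gap_count = 1L, gap_index = 100 / interface_length_um))
  }
  runs <- runs[order(runs[, 1]), , drop = FALSE]
  if (any(runs[, 2] < runs[, 1]) || any(runs[, 1] < -1e-9) ||
      any(runs[, 2] > interface_length_um + 1e-9))
    stopf("runs must be ordered intervals within the interface")
  if (nrow(runs) > 1 && any(runs[-1, 1] < runs[-nrow(runs), 2] - 1e-9))
    stopf("runs must be disjoint")
  len <- runs[, 2] - runs[, 1]
  total <- sum(len)
  cont <- sum(len[len >= min_run_um])
  gaps <- if (nrow(runs) > 1) runs[-1, 1] - runs[-nrow(runs), 2] else numeric(0)
  gap_count <- sum(gaps >= min_gap_um)
  list(stained_um = total,
       continuous_percent = if (total > 0) 100 * cont / total else NA_real_,
       discontinuous_percent = if (total > 0) 100 * (total - cont) / total else NA_real_,
       n_runs = nrow(runs), gap_count = as.integer(gap_count),
       gap_index = 100 * gap_count / interface_length_um)
}

#' Quantify junction continuity from a VEC / compartment image pair
#'
#' Recovers the interface centerlines by thinning the compartment (CD31)
#' mask, projects each connected VEC-mask component onto the interface chain
#' that receives most of its pixels, converts the projected arc-length spans
#' into stained run intervals, and applies \code{\link{junction_continuity}}
#' per interface chain. Because runs are separate connected components, an
#' unstained gap between two runs can never be bridged by the projection.
#'
#' @param vec a \code{\link{raster_image}} of the VEC channel.
#' @param cd31 a \code{\link{raster_image}} or \code{\link{binary_mask}} of
#'   the junction compartment; images are Otsu-thresholded.
#' @param low,high optional hysteresis thresholds for VEC.
#' @param match_radius_px maximum distance between a VEC pixel and the
#'   interface chain for the pixel to take part in the projection.
#' @param min_run_um,min_gap_um passed to \code{\link{junction_continuity}}.
#' @param gap_evidence_px an uncovered stretch counts as a gap only if some
#'   of its positions lie at least this far from every VEC-stained pixel;
#'   stretches hugging the stain are projection artifacts and are closed.
#' @return list of class \code{junction_result}: \code{interfaces} (data
#'   frame per interface chain), \code{totals} (stained length, run count,
#'   gap count, gap index, continuous percent).
#' @export
junction_pipeline <- function(vec, cd31, low = NULL, high = NULL,
                              match_radius_px = 4, min_run_um = 2,
                              min_gap_um = 0.5, gap_evidence_px = 2.6) {
  psz <- pixel_size_of(vec)
  cm <- if (inherits(cd31, "binary_mask") || is.logical(cd31)) as_mask(cd31)
        else as_mask(otsu_threshold(cd31))
  if (!any(cm)) stopf("empty junction compartment")
  px <- as_pixels(vec)
  if (is.null(low) || is.null(high)) {
    def <- vec_hysteresis_defaults(px, cm)
    if (is.null(low)) low <- def$low
    if (is.null(high)) high <- def$high
  }
  vm <- if (is.finite(high)) as_mask(hysteresis_threshold(px, low, high)) & cm
        else matrix(FALSE, nrow(px), ncol(px))
  # prune thinning spurs so interfaces are not split at spurious branch
  # points (a split inside an unstained stretch would hide that gap)
  skel <- prune_skeleton(skeletonize(binary_mask(cm, psz)),
                         binary_mask(cm, psz))
  chains <- Filter(function(sg) nrow(sg) >= 3, skel$segments)
  # arc-length coordinate along each chain
  arcs <- lapply(chains, function(sg) {
    d <- diff(sg[, 1:2, drop = FALSE])
    cumsum(c(0, sqrt(d[, 1]^2 + d[, 2]^2))) * psz
  })
  # project every VEC pixel onto its nearest chain pixel (within the match
  # radius); a chain position is stained when at least one VEC pixel projects
  # onto it. Spill past a run end is at most ~1 px, so unstained gaps are
  # never bridged.
  chain_xy <- do.call(rbind, lapply(seq_along(chains), function(i)
    cbind(chains[[i]][, "x"], chains[[i]][, "y"], i,
          seq_len(nrow(chains[[i]])))))
  votes <- lapply(chains, function(sg) rep(0L, nrow(sg)))
  if (any(vm) && length(chains)) {
    w <- which(vm, arr.ind = TRUE)
    pxy <- cbind(w[, 2] - 1, w[, 1] - 1)
    d2 <- outer(pxy[, 1], chain_xy[, 1], `-`)^2 +
          outer(pxy[, 2], chain_xy[, 2], `-`)^2
    nearest <- apply(d2, 1, which.min)
    dist2 <- d2[cbind(seq_len(nrow(pxy)), nearest)]
    ok <- dist2 <= match_radius_px^2
    for (k in which(ok)) {
      ci <- chain_xy[nearest[k], 3]
      votes[[ci]][chain_xy[nearest[k], 4]] <- votes[[ci]][chain_xy[nearest[k], 4]] + 1L
    }
  }
  covered <- lapply(votes, function(v) v >= 1L)
  # classify uncovered stretches by image evidence rather than length:
  # a stretch is a genuine gap only if some of its positions are far from
  # any VEC stain; stretches hugging the stain (projection dropout inside a
  # run, spill slack at run ends and chain ends) are closed
  dvec <- if (any(vm)) {
    EBImage::distmap(matrix(as.numeric(!vm), nrow(vm), ncol(vm)))
  } else matrix(Inf, nrow(vm), ncol(vm))
  covered <- lapply(seq_along(covered), function(i) {
    cv <- covered[[i]]
    sg <- chains[[i]]
    r <- rle(cv)
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    for (k in seq_along(r$values)) {
      if (r$values[k]) next
      ij <- cbind(sg[starts[k]:ends[k], "y"] + 1, sg[starts[k]:ends[k], "x"] + 1)
      if (max(dvec[ij]) < gap_evidence_px) r$values[k] <- TRUE
    }
    inverse.rle(r)
  })
  rows <- list()
  boundary_gaps <- NULL
  for (i in seq_along(chains)) {
    arc <- arcs[[i]]
    L <- arc[length(arc)]
    if (L <= 0) next
    r <- rle(covered[[i]])
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    runs <- NULL
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      if (arc[ends[k]] > arc[starts[k]])
        runs <- rbind(runs, c(arc[starts[k]], arc[ends[k]]))
    }
    # a gap abutting a chain end (where the branch zone of a node consumed
    # the short run beyond it, or the chain was split inside the gap)
    # survives the evidence test above as a boundary uncovered stretch;
    # collect it for counting at the field level, where remnants of one gap
    # split across two chains are merged
    nk <- length(r$values)
    for (k in unique(c(1L, nk))) {
      if (nk > 1 && !r$values[k] &&
          arc[ends[k]] - arc[starts[k]] >= min_gap_um) {
        sgk <- chains[[i]][starts[k]:ends[k], , drop = FALSE]
        boundary_gaps <- rbind(boundary_gaps,
                               c(colMeans(sgk[, 1:2, drop = FALSE]), i))
      }
    }
    cc <- junction_continuity(runs, L, min_run_um, min_gap_um)
    rows[[length(rows) + 1L]] <- data.frame(
      interface_length_um = L, stained_um = cc$stained_um,
      n_runs = cc$n_runs, gap_count = cc$gap_count, gap_index = cc$gap_index,
      continuous_percent = cc$continuous_percent,
      discontinuous_percent = cc$discontinuous_percent)
  }
  interfaces <- if (length(rows)) do.call(rbind, rows) else
    data.frame(interface_length_um = numeric(0), stained_um = numeric(0),
               n_runs = integer(0), gap_count = integer(0),
               gap_index = numeric(0), continuous_percent = numeric(0),
               discontinuous_percent = numeric(0))
  tot_len <- sum(interfaces$interface_length_um)
  tot_stained <- sum(interfaces$stained_um)
  # single-linkage clustering of boundary gap remnants: halves of one gap
  # split across two chains lie within a node zone of each other
  n_boundary <- 0L
  if (!is.null(boundary_gaps)) {
    m <- nrow(boundary_gaps)
    grp <- seq_len(m)
    if (m > 1) {
      for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        if (sqrt(sum((boundary_gaps[i, 1:2] - boundary_gaps[j, 1:2])^2)) <= 5)
          grp[grp == grp[j]] <- grp[i]
      }
    }
    n_boundary <- length(unique(grp))
  }
  tot_gaps <- sum(interfaces$gap_count) + n_boundary
  totals <- data.frame(
    n_interfaces = nrow(interfaces),
    interface_length_um = tot_len,
    stained_um = tot_stained,
    n_runs = sum(interfaces$n_runs),
    gap_count = tot_gaps,
    gap_index = if (tot_len > 0) 100 * tot_gaps / tot_len else NA_real_,
    continuous_percent = if (tot_stained > 0)
      100 * sum(interfaces$stained_um * interfaces$continuous_percent / 100,
                na.rm = TRUE) / tot_stained else NA_real_
  )
  structure(list(interfaces = interfaces, totals = totals,
                 thresholds = c(low = low, high = high)),
            class = "junction_result")
}

#' @export
print.junction_result <- function(x, ...) {
  cat(sprintf("<junction_result> %d interfaces, %.1f um stained, %d gaps\n",
              x$totals$n_interfaces, x$totals$stained_um, x$totals$gap_count))
  invisible(x)
}
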