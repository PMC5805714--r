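# ImageJ-style particle analysis ----------------------------------------------

# Moore boundary tracing of one labeled region; returns the closed boundary
# chain length with orthogonal steps weighted 1 and diagonal steps sqrt(2).
trace_perimeter <- function(region) {
  # region: logical matrix (padded by caller so no foreground touches border)
  w <- which(region, arr.ind = TRUE)
  if (nrow(w) == 1) return(4)         # single pixel: unit square boundary
  # start at the topmost-leftmost pixel, backtrack points west
  ord <- order(w[, 1], w[, 2])
  start <- w[ord[1], ]
  # Moore neighbourhood in clockwise order starting east
  offs <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  # index of the offset pointing from current pixel to its backtrack pixel
  dir_index <- function(d) which(offs[, 1] == d[1] & offs[, 2] == d[2])
  cur <- start
  back_dir <- dir_index(c(0, -1))     # came from the west
  perim <- 0
  first_move <- NULL
  repeat {
    found <- FALSE
    for (k in 1:8) {
      di <- ((back_dir + k - 1L) %% 8L) + 1L
      cand <- cur + offs[di, ]
      if (region[cand[1], cand[2]]) {
        step <- offs[di, ]
        perim <- perim + if (all(step != 0)) sqrt(2) else 1
        prev <- cur
        cur <- cand
        back_dir <- dir_index(prev - cur)
        if (is.null(first_move)) {
          first_move <- c(prev, cur)
        } else if (all(c(prev, cur) == first_move)) {
          # closed the boundary and repeated the first move
          return(perim - if (all(step != 0)) sqrt(2) else 1)
        }
        found <- TRUE
        break
      }
    }
    if (!found) return(4)             # isolated pixel reached via pruning
  }
}

#' Analyze particles: size and circularity filtered connected structures
#'
#' Labels the mask by 8-connectivity and measures each particle's calibrated
#' area, boundary-traced perimeter (orthogonal steps weighted 1, diagonal
#' steps \eqn{\sqrt 2}) and circularity \eqn{4\pi A / P^2} (clipped at 1).
#' Particles with area at or below \code{min_size_um2} or circularity outside
#' \code{circularity_range} are discarded, mirroring ImageJ's Analyze
#' Particles size/circularity settings.
#'
#' @param mask a \code{\link{binary_mask}}.
#' @param min_size_um2 minimum calibrated area; particles must exceed it.
#' @param circularity_range inclusive \code{c(lo, hi)} within \code{[0, 1]}.
#' @return list with \code{particles} (data frame: id, area_um2,
#'   perimeter_um, circularity, centroid_x, centroid_y), \code{count}, and
#'   \code{mean_area_um2} (\code{NA} when no particle passes - missing, not
#'   zero).
#' @export
analyze_particles <- function(mask, min_size_um2 = 10,
                              circularity_range = c(0, 1)) {
  m <- as_mask(mask)
  psz <- pixel_size_of(mask)
  lab <- label8(m)
  n <- max(lab)
  if (n == 0) {
    return(list(particles = data.frame(id = integer(0), area_um2 = numeric(0),
                                       perimeter_um = numeric(0),
                                       circularity = numeric(0),
                                       centroid_x = numeric(0),
                                       centroid_y = numeric(0)),
                count = 0L, mean_area_um2 = NA_real_))
  }
  padded <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  padded[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- lab
  rows <- lapply(seq_len(n), function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    area <- nrow(w) * psz^2
    perim <- trace_perimeter(padded == l) * psz
    circ <- if (perim > 0) min(4 * pi * area / perim^2, 1) else 1
    data.frame(id = l, area_um2 = area, perimeter_um = perim,
               circularity = circ,
               centroid_x = mean(w[, 2]) - 1, centroid_y = mean(w[, 1]) - 1)
  })
  df <- do.call(rbind, rows)
  keep <- df$area_um2 > min_size_um2 &
    df$circularity >= circularity_range[1] &
    df$circularity <= circularity_range[2]
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  list(particles = df, count = nrow(df),
       mean_area_um2 = if (nrow(df)) mean(df$area_um2) else NA_real_)
}
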