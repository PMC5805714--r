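# Coordinate convention used throughout: a pixel grid of `shape = c(nrow, ncol)`
# holds intensities in a base R matrix indexed [row, col]; continuous image
# coordinates are 0-based with x = col - 1, y = row - 1, and a pixel's center
# sits at integer (x, y). Lengths/areas convert to micrometres via
# `pixel_size_um`.

#' Evaluate an expression under a local random seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' random state afterwards, so generators never disturb global randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Label connected components under 8-connectivity
#'
#' EBImage's `bwlabel()` uses 4-connectivity; vessel structures, skeleton
#' chains and hysteresis components are defined on the 8-neighbourhood, so
#' diagonal-touching 4-components are merged with a union-find pass.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of labels (0 = background).
#' @keywords internal
label8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n <= 1L) return(lab)
  # pairs of distinct labels touching diagonally
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  compact <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- compact[lab[lab > 0L]]
  out
}

# 2D convolution with replicate padding (avoids EBImage's circular wrap).
conv2_replicate <- function(m, kernel) {
  ry <- (nrow(kernel) - 1L) %/% 2L
  rx <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, ry), seq_len(nr), rep(nr, ry))
  ci <- c(rep(1L, rx), seq_len(nc), rep(nc, rx))
  padded <- m[ri, ci, drop = FALSE]
  res <- EBImage::filter2(padded, kernel)
  matrix(res[ry + seq_len(nr), rx + seq_len(nc)], nr, nc)
}

# Separable convolution from 1D kernels (ky along rows/y, kx along cols/x).
conv_sep <- function(m, ky, kx) {
  conv2_replicate(m, outer(ky, kx))
}

# FNV-1a hash of a character scalar, returned as 8 hex digits. Used for the
# run-manifest configuration fingerprint. 32-bit arithmetic is done on
# 16-bit limbs so every intermediate stays exactly representable in doubles.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Chebyshev-dilate a logical mask by `r` pixels (square structuring element).
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask != 0)
  k <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "box")
  EBImage::dilate(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), k) > 0.5
}
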