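# Independent brute-force oracles used to validate the implementation paths.
# These are deliberately written as direct, slow computations that share no
# code with the package internals.

# Exhaustive Otsu: try all 256 candidate cuts on the binned pixel values and
# pick the one maximizing between-class variance, computing the class means
# directly from the partitioned pixel values.
oracle_otsu_threshold <- function(px) {
  lo <- min(px); hi <- max(px)
  w <- (hi - lo) / 256
  bin <- pmin(255L, floor((px - lo) / w))
  best <- -Inf; best_k <- NA
  for (k in 1:255) {
    v0 <- px[bin < k]; v1 <- px[bin >= k]
    if (!length(v0) || !length(v1)) next
    bcv <- length(v0) * length(v1) * (mean(v0) - mean(v1))^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  list(threshold = lo + best_k * w, mask = matrix(bin >= best_k, nrow(px), ncol(px)))
}

# O(n^2) Euclidean distance transform: per foreground pixel, the minimum
# distance over every background pixel.
oracle_edt <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((fg[i, 1] - bg[, 1])^2 + (fg[i, 2] - bg[, 2])^2))
  }
  out
}

# Full permutation enumeration of the two-sided Spearman p-value.
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  n <- length(x)
  perm_rec <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(perm_rec(ry), function(p) cor(rx, p), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Summation-form Pearson chi-square over the four cells.
oracle_chi2_sum <- function(a, b, c, d) {
  obs <- c(a, b, c, d)
  n <- sum(obs)
  rs <- c(a + b, a + b, c + d, c + d)
  cs <- c(a + c, b + d, a + c, b + d)
  e <- rs * cs / n
  sum((obs - e)^2 / e)
}

# 8-neighbour count by explicit shifting (independent of package internals).
oracle_neighbor_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    if (dr == 1 && dc == 1) next
    out <- out + p[dr + 1:nr, dc + 1:nc]
  }
  out
}

# Convenience: noise-free single straight horizontal tube truth + rendering.
make_straight_vessel <- function(shape = c(64L, 128L), y = 32, radius = 4,
                                 perfused = TRUE, pixel_size_um = 1) {
  pl <- cbind(x = c(0, shape[2] - 1), y = c(y, y))
  vessel_truth(list(list(pl)), list(list(radius)), perfused, shape,
               pixel_size_um = pixel_size_um)
}

# Y-shaped tree: one horizontal parent, one oblique child from its middle.
make_y_vessel <- function(shape = c(96L, 96L)) {
  parent <- cbind(x = c(5, 90), y = c(48, 48))
  child <- cbind(x = c(47.5, 85), y = c(48, 85))
  vessel_truth(list(list(parent, child)), list(list(4, 4)), TRUE, shape,
               branch_points = matrix(c(47.5, 48, 1), 1, 3,
                                      dimnames = list(NULL, c("x", "y", "vessel"))))
}
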