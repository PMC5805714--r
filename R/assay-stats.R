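# Assay arithmetic and the two printed-result statistics ----------------------

#' Caliper tumor volume
#'
#' \eqn{V = width^2 \times length / 2} (mm\eqn{^3}), the standard ellipsoid
#' approximation for caliper measurements.
#'
#' @param width_mm,length_mm caliper width and length in mm (vectorized).
#' @return volume in mm\eqn{^3}.
#' @examples
#' tumor_volume(10, 10)   # 500
#' @export
tumor_volume <- function(width_mm, length_mm) {
  if (any(width_mm < 0) || any(length_mm < 0))
    stopf("width and length must be non-negative")
  width_mm^2 * length_mm / 2
}

#' Relative quantity by the 2^-ddCt method
#'
#' Per sample, \eqn{\Delta Ct = Ct_{target} - Ct_{reference}};
#' \eqn{\Delta\Delta Ct} is taken relative to the calibrator, chosen as the
#' sample with the largest \eqn{\Delta Ct} (the lowest expression), so the
#' calibrator's Rq is exactly 1 and every Rq is at least 1.
#'
#' @param ct_target target-gene Ct values.
#' @param ct_reference reference-gene Ct values (same length).
#' @return numeric vector of relative quantities \eqn{2^{-\Delta\Delta Ct}}.
#' @examples
#' rq_ddct(c(25, 22), c(5, 2))   # both dCt = 20: c(1, 1)
#' @export
rq_ddct <- function(ct_target, ct_reference) {
  if (length(ct_target) == 0) stopf("no samples")
  if (length(ct_target) != length(ct_reference))
    stopf("target and reference Ct vectors differ in length")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stopf("Ct values must be finite")
  dct <- ct_target - ct_reference
  2^-(dct - max(dct))
}

#' Immunohistochemistry H-score
#'
#' Product of the percentage of stained cells and the staining intensity
#' grade (1-3), giving a score in \code{[0, 300]}.
#'
#' @param percent_stained percentage in \code{[0, 100]} (vectorized).
#' @param intensity integer grade in \code{{1, 2, 3}}.
#' @return H-score.
#' @export
h_score <- function(percent_stained, intensity) {
  if (any(percent_stained < 0) || any(percent_stained > 100))
    stopf("percent_stained must lie in [0, 100]")
  if (any(!intensity %in% c(1, 2, 3)))
    stopf("intensity grade must be 1, 2 or 3")
  percent_stained * intensity
}

#' Fit a standard curve
#'
#' Least-squares line of measured signal against known quantity, optionally
#' with the quantities log-transformed (e.g. log2 for qPCR dilution series,
#' where the slope is Ct units per doubling).
#'
#' @param x known quantities (for log mode, all > 0), strictly monotone.
#' @param y measured signal (Ct, fluorescence).
#' @param log_base if non-\code{NULL}, fit against \code{log(x, log_base)}.
#' @return object of class \code{standard_curve} with slope, intercept and
#'   the fit points.
#' @export
fit_standard_curve <- function(x, y, log_base = NULL) {
  if (length(x) < 2 || length(x) != length(y))
    stopf("a standard curve needs at least 2 (x, y) points")
  if (is.unsorted(x) && is.unsorted(rev(x)))
    stopf("x must be strictly monotone")
  xt <- if (!is.null(log_base)) {
    if (any(x <= 0)) stopf("log-mode standard curve requires positive x")
    log(x, base = log_base)
  } else x
  if (max(xt) == min(xt)) stopf("singular fit: constant x")
  fit <- lm(y ~ xt)
  structure(list(x = x, y = y, log_base = log_base,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1])),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %d points, slope %.4g, intercept %.4g%s\n",
              length(x$x), x$slope, x$intercept,
              if (!is.null(x$log_base)) sprintf(" (log%g x)", x$log_base) else ""))
  invisible(x)
}

#' Interpolate quantities from a standard curve
#'
#' Inverts the fitted line to map measured signals back to quantities.
#' Signals outside the calibrated range are extrapolated and flagged in the
#' \code{"extrapolated"} attribute.
#'
#' @param curve a \code{\link{fit_standard_curve}} result.
#' @param y_new measured signals.
#' @return quantities, with a logical attribute \code{extrapolated}.
#' @export
interpolate_curve <- function(curve, y_new) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stopf("cannot invert a flat standard curve")
  xt <- (y_new - curve$intercept) / curve$slope
  out <- if (!is.null(curve$log_base)) curve$log_base^xt else xt
  attr(out, "extrapolated") <- y_new < min(curve$y) | y_new > max(curve$y)
  out
}

#' ChIP signal relative to input
#'
#' Quantities are read off the standard curve from the Ct values; the input
#' quantity is scaled by \code{1 / input_fraction} (e.g. a 1\% input aliquot
#' scales 100-fold); the IgG (mock) quantity, expressed relative to the same
#' scaled input, is subtracted, and the result is floored at 0.
#'
#' @param ct_chip,ct_input,ct_igg Ct values of the ChIP, input and IgG
#'   reactions.
#' @param curve the \code{\link{fit_standard_curve}} calibration shared by
#'   all three reactions.
#' @param input_fraction fraction of lysate stored as input, in (0, 1].
#' @return signal relative to input (fraction, >= 0).
#' @export
chip_relative_to_input <- function(ct_chip, ct_input, ct_igg, curve,
                                   input_fraction = 0.01) {
  if (input_fraction <= 0 || input_fraction > 1)
    stopf("input_fraction must lie in (0, 1]")
  q <- interpolate_curve(curve, c(ct_chip, ct_input, ct_igg))
  q_input <- q[2] / input_fraction
  if (!is.finite(q_input) || q_input <= 0)
    stopf("non-positive input quantity")
  max(0, q[1] / q_input - q[3] / q_input)
}

#' 2x2 contingency table
#'
#' @param a,b first row (group 1: outcome yes / no).
#' @param c,d second row (group 2: outcome yes / no).
#' @return object of class \code{table2x2}.
#' @export
table2x2 <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(v < 0) || any(v != round(v))) stopf("counts must be non-negative integers")
  if (sum(v) == 0) stopf("empty table")
  structure(list(a = a, b = b, c = c, d = d), class = "table2x2")
}

#' Pearson chi-square test for a 2x2 table
#'
#' The product form \eqn{\chi^2 = N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}
#' with the p-value from the chi-square distribution with 1 df. No
#' continuity correction is applied by default; Yates' correction is
#' available via \code{correct = TRUE}.
#'
#' @param t a \code{\link{table2x2}}.
#' @param correct apply Yates' continuity correction.
#' @return list: \code{chi2}, \code{p}, \code{df = 1}.
#' @examples
#' pearson_chi2_2x2(table2x2(35, 11, 17, 17))$p   # ~0.016
#' @export
pearson_chi2_2x2 <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "table2x2"))
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  n <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0))
    stopf("a margin is zero: expected counts of 0")
  num <- abs(a * d - b * cc)
  if (correct) num <- max(0, num - n / 2)
  chi2 <- n * num^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), df = 1L)
}

# iterative generator of all permutations of 1..n (lexicographic), in chunks
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the Pearson correlation of midranks. For \code{n <= exact_n} the
#' two-sided p-value is computed by full enumeration of all \code{n!}
#' permutations (\eqn{P(|\rho_{perm}| \ge |\rho_{obs}|)}); for larger n the
#' t-approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} with \eqn{n-2} df
#' is used.
#'
#' @param x,y numeric vectors, length >= 3.
#' @param exact_n largest n for which the permutation p-value is enumerated.
#' @return list: \code{rho}, \code{p}, \code{method}.
#' @export
spearman_correlation <- function(x, y, exact_n = 10) {
  n <- length(x)
  if (n != length(y)) stopf("x and y differ in length")
  if (n < 3) stopf("at least 3 pairs are required")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stopf("constant vector: rank variance is zero")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    perms <- all_permutations(n)
    sx <- rx - mean(rx); sy <- ry - mean(ry)
    denom <- sqrt(sum(sx^2) * sum(sy^2))
    rho_perm <- (matrix(sy[perms], nrow(perms)) %*% sx) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), method = method)
}
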