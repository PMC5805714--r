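# Perfusion, leakage and VEC/CD31 overlap -------------------------------------

#' Perfusion fraction from CD31 / lectin object overlap
#'
#' Labels CD31\eqn{^+} structures (8-connectivity, size-filtered as in
#' particle analysis) and calls a structure double-positive
#' (CD31\eqn{^+}lectin\eqn{^+}) when at least \code{overlap_fraction} of its
#' pixels are lectin-positive. Perfusion is the percentage of double-positive
#' structures among all CD31\eqn{^+} structures.
#'
#' @param cd31_mask,lectin_mask \code{\link{binary_mask}}s of the same shape.
#' @param min_size_um2 minimum structure area.
#' @param overlap_fraction pixel-overlap fraction required to call a
#'   structure double-positive (the classification is object-based, not
#'   intensity-based; any-overlap would be noise-fragile, so a 30\%
#'   default is used and reported).
#' @return list of class \code{perfusion_result}: \code{n_cd31},
#'   \code{n_double}, \code{percent_perfused}.
#' @export
perfusion_fraction <- function(cd31_mask, lectin_mask, min_size_um2 = 10,
                               overlap_fraction = 0.3) {
  cm <- as_mask(cd31_mask); lm <- as_mask(lectin_mask)
  if (!all(dim(cm) == dim(lm))) stopf("masks must have the same shape")
  psz <- pixel_size_of(cd31_mask)
  lab <- label8(cm)
  n <- max(lab)
  if (n > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n) * psz^2
    ids <- which(areas > min_size_um2)
  } else ids <- integer(0)
  if (length(ids) == 0)
    stopf("no CD31+ structures: perfusion percentage is undefined")
  dbl <- vapply(ids, function(l) {
    px <- lab == l
    mean(lm[px]) >= overlap_fraction
  }, logical(1))
  structure(list(n_cd31 = length(ids), n_double = sum(dbl),
                 percent_perfused = 100 * sum(dbl) / length(ids),
                 overlap_fraction = overlap_fraction),
            class = "perfusion_result")
}

#' @export
print.perfusion_result <- function(x, ...) {
  cat(sprintf("<perfusion_result> %d/%d CD31+ structures lectin+ (%.1f%%)\n",
              x$n_double, x$n_cd31, x$percent_perfused))
  invisible(x)
}

#' Dextran leakage index
#'
#' Vessel leakage is the ratio of background-subtracted extravasated dextran
#' fluorescence to the number of perfused vessels. The extravascular
#' compartment is everything outside the vessel mask dilated by
#' \code{dilate_px} (absorbing boundary bleed); the background is a
#' percentile of the extravascular intensities (the 50th by default) and is
#' subtracted with clipping at zero before summation.
#'
#' @param dextran a \code{\link{raster_image}} of the dextran channel.
#' @param vessel_mask \code{\link{binary_mask}} of perfused vessels.
#' @param perfused_count number of perfused vessels (> 0).
#' @param background_percentile percentile (0-100) of extravascular pixels
#'   used as background.
#' @param dilate_px vessel-mask dilation before defining "extravascular".
#' @return list of class \code{leakage_result}: \code{extravascular_intensity},
#'   \code{perfused_count}, \code{leakage_index}.
#' @export
leakage_index <- function(dextran, vessel_mask, perfused_count,
                          background_percentile = 50, dilate_px = 1) {
  if (length(perfused_count) != 1 || perfused_count <= 0)
    stopf("'perfused_count' must be a positive count")
  px <- as_pixels(dextran)
  vm <- as_mask(vessel_mask)
  if (!all(dim(px) == dim(vm))) stopf("image and mask must have the same shape")
  extra <- !dilate_mask(vm, dilate_px)
  vals <- px[extra]
  bg <- if (length(vals)) quantile(vals, background_percentile / 100, names = FALSE) else 0
  total <- sum(pmax(vals - bg, 0))
  structure(list(extravascular_intensity = total,
                 perfused_count = perfused_count,
                 background = bg,
                 leakage_index = total / perfused_count),
            class = "leakage_result")
}

#' @export
print.leakage_result <- function(x, ...) {
  cat(sprintf("<leakage_result> extravascular %.3g over %d perfused vessels: index %.4g\n",
              x$extravascular_intensity, x$perfused_count, x$leakage_index))
  invisible(x)
}

#' VEC / CD31 stained-area ratio
#'
#' Percentage of the CD31-stained area also VEC-stained:
#' \code{100 * |VEC intersect CD31| / |CD31|} by pixel counts (the
#' image-calculator intersection of coincident stained regions).
#'
#' @param vec_mask,cd31_mask \code{\link{binary_mask}}s of the same shape.
#' @return percentage in \code{[0, 100]}.
#' @export
vec_area_fraction <- function(vec_mask, cd31_mask) {
  vm <- as_mask(vec_mask); cm <- as_mask(cd31_mask)
  if (!all(dim(vm) == dim(cm))) stopf("masks must have the same shape")
  if (!any(cm)) stopf("empty CD31 mask: area ratio is undefined")
  100 * sum(vm & cm) / sum(cm)
}
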