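#' Acquisition noise model for synthetic micrographs
#'
#' Describes the degradations applied to a noise-free rendering, in order:
#' Gaussian PSF blur, optional Poisson photon resampling, then additive
#' background and Gaussian read noise. Identical parameters and seed always
#' produce bit-identical images.
#'
#' @param psf_sigma_px standard deviation of the Gaussian PSF in pixels
#'   (>= 0; 0 disables blur).
#' @param gaussian_sd standard deviation of additive Gaussian noise on the
#'   normalized intensity scale (>= 0).
#' @param poisson logical; if \code{TRUE}, intensities are resampled as
#'   Poisson photon counts (\code{photons_per_unit} expected photons at
#'   intensity 1) and rescaled.
#' @param background_level constant background offset (>= 0).
#' @param seed integer seed; generators never touch global random state.
#' @param photons_per_unit photon budget defining Poisson shot-noise strength.
#' @return an object of class \code{noise_model}.
#' @examples
#' noise_model(psf_sigma_px = 1, gaussian_sd = 0.02)
#' @export
noise_model <- function(psf_sigma_px = 1, gaussian_sd = 0.02, poisson = TRUE,
                        background_level = 0.05, seed = 1L,
                        photons_per_unit = 200) {
  for (nm in c("psf_sigma_px", "gaussian_sd", "background_level", "photons_per_unit")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stopf("'%s' must be a single non-negative number", nm)
  }
  structure(
    list(psf_sigma_px = psf_sigma_px, gaussian_sd = gaussian_sd,
         poisson = isTRUE(poisson), background_level = background_level,
         seed = as.integer(seed), photons_per_unit = photons_per_unit),
    class = "noise_model"
  )
}

#' The no-op noise model (identity degradation)
#' @return a \code{noise_model} that leaves images unchanged.
#' @export
noise_none <- function(seed = 1L) {
  noise_model(psf_sigma_px = 0, gaussian_sd = 0, poisson = FALSE,
              background_level = 0, seed = seed)
}

#' Apply PSF blur and acquisition noise to an image
#'
#' Blur (mass-conserving discrete Gaussian), then optional Poisson
#' resampling, then background offset plus additive Gaussian noise, clipped
#' at zero. Deterministic under the model's seed; the caller's random state
#' is untouched.
#'
#' @param image a \code{\link{raster_image}} (or bare matrix).
#' @param noise a \code{\link{noise_model}}.
#' @return a \code{raster_image} with the same metadata.
#' @export
apply_noise <- function(image, noise) {
  stopifnot(inherits(noise, "noise_model"))
  px <- as_pixels(image)
  if (any(!is.finite(px)) || any(px < 0))
    stopf("apply_noise() requires a finite, non-negative image")
  out <- px
  if (noise$psf_sigma_px > 0) {
    s <- noise$psf_sigma_px
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    # FFT-based convolution can leave values a few ulp below zero
    out <- pmax(conv_sep(out, k, k), 0)
  }
  if (noise$poisson || noise$gaussian_sd > 0 || noise$background_level > 0) {
    out <- with_local_seed(noise$seed, {
      tmp <- out
      if (noise$poisson) {
        g <- noise$photons_per_unit
        tmp <- matrix(rpois(length(tmp), lambda = tmp * g) / g,
                      nrow(tmp), ncol(tmp))
      }
      tmp <- tmp + noise$background_level
      if (noise$gaussian_sd > 0) {
        tmp <- tmp + matrix(rnorm(length(tmp), sd = noise$gaussian_sd),
                            nrow(tmp), ncol(tmp))
      }
      tmp
    })
  }
  out <- pmax(out, 0)
  if (inherits(image, "raster_image")) {
    raster_image(out, image$pixel_size_um, image$channel, image$bit_depth)
  } else {
    out
  }
}
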