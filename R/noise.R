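#' Standard deviation of the iCCD measurement at a pixel
#'
#' Propagates the intensifier noise budget for an expected photon count
#' \eqn{P} incident on the photocathode:
#' \deqn{\sigma = \sqrt{\sigma_{read}^2 + F^2 M^2
#'   (\sigma_{signal}^2 + \sigma_{dark}^2 + \sigma_{clc}^2)},\qquad
#'   \sigma_{signal}^2 = DQE \cdot P,}
#' in post-amplification output counts. The gain is treated as constant
#' within the gate (the time dependence of the gain is carried by the
#' gate profile in the forward model, so the noise module only sees the
#' gate-integrated expected photon count).
#'
#' @param clean_signal Expected photons incident at the pixel (before
#'   quantum efficiency), >= 0; vectorized.
#' @param det A [detector_config()].
#' @param dur Gated exposure duration (s) used to accumulate dark noise;
#'   defaults to \code{det$exposure_s}.
#' @return Standard deviation(s) in output counts.
#' @export
noise_sigma <- function(clean_signal, det, dur = det$exposure_s) {
  if (any(!is.finite(clean_signal)) || any(clean_signal < 0))
    stop("clean_signal must be finite and >= 0", call. = FALSE)
  if (dur < 0) stop("dur must be >= 0", call. = FALSE)
  var_in <- det$dqe * clean_signal + det$dark_rate * dur + det$sigma_clc^2
  sqrt(det$sigma_readout^2 + det$noise_factor^2 * det$gain^2 * var_in)
}

#' Sample intensifier noise onto a clean iCCD image
#'
#' Draws each pixel from the Gaussian approximation of the iCCD noise
#' model, \eqn{S_i \sim N(s_i, \sigma_i)} with \eqn{\sigma_i} from
#' [noise_sigma()], then rescales back to the photon scale of the input
#' so that the noisy image has the clean image as its mean. Negative
#' values are retained: readout noise is signed.
#'
#' The \code{"poisson"} mode replaces the Gaussian signal term with a
#' genuinely Poisson-shaped draw of matching mean and variance (the shot
#' noise on \eqn{DQE \cdot P} photoelectrons, scaled by the excess noise
#' factor), as a distributional cross-check of the approximation.
#'
#' @param clean Clean iCCD image (photons), from [simulate_iccd()].
#' @param det A [detector_config()].
#' @param seed RNG seed; identical inputs and seed give identical output.
#' @param mode \code{"gaussian"} (default) or \code{"poisson"}.
#' @return Noisy image matrix with attribute \code{is_noisy = TRUE} and
#'   \code{seed} recording the seed used.
#' @export
sample_noisy_iccd <- function(clean, det, seed = NULL,
                              mode = c("gaussian", "poisson")) {
  mode <- match.arg(mode)
  if (any(clean < 0)) stop("clean image must be non-negative", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  npix <- length(clean)
  scale <- det$gain * det$dqe            # counts per incident photon
  if (mode == "gaussian") {
    sd_counts <- noise_sigma(as.vector(clean), det)
    noisy <- clean + matrix(stats::rnorm(npix, 0, sd_counts / scale),
                            nrow(clean))
  } else {
    lambda <- det$dqe * as.vector(clean)
    shot <- det$noise_factor * (stats::rpois(npix, lambda) - lambda) / det$dqe
    var_add <- det$dark_rate * det$exposure_s + det$sigma_clc^2
    sd_counts <- sqrt(det$sigma_readout^2 +
                        det$noise_factor^2 * det$gain^2 * var_add)
    noisy <- clean + matrix(shot + stats::rnorm(npix, 0, sd_counts / scale),
                            nrow(clean))
  }
  attr(noisy, "is_noisy") <- TRUE
  attr(noisy, "seed") <- seed
  noisy
}
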