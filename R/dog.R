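#' Derivative-of-Gaussian (DoG) bias function
#'
#' The odd-symmetric curve used throughout serial-dependence work to
#' parameterize bias as a function of the orientation difference between
#' consecutive stimuli:
#' \deqn{y(x) = x \, A \, w \, c \, e^{-(wx)^2}, \qquad c = \sqrt{2e},}
#' where `A` is the amplitude and `w` the inverse-width. The normalization
#' `c = sqrt(2e)` is chosen so that the curve's peak value equals `A`
#' (attained at `x = 1/(w sqrt(2))`), making the amplitude directly
#' interpretable as the peak bias in degrees.
#'
#' @param x Orientation difference in degrees (any real vector).
#' @param amplitude Peak bias `A` in degrees; positive = attraction toward the
#'   previous stimulus, negative = repulsion.
#' @param width Inverse width `w` in 1/degrees; must be positive.
#' @return Bias in degrees, same length as `x`.
#' @examples
#' dog(seq(-90, 90, 10), amplitude = 4.5, width = 0.04)
#' @export
dog <- function(x, amplitude, width) {
  if (!is.numeric(width) || any(width <= 0)) {
    rlang::abort("`width` must be positive", class = "serialdep_error_dog_width")
  }
  x * amplitude * width * sqrt(2 * exp(1)) * exp(-(width * x)^2)
}

#' Full width at half maximum of a DoG curve
#'
#' Found numerically: the two roots of `dog(x) = A/2` that bracket the peak
#' are located by root-finding on a dense interval and their distance doubled
#' (the curve is odd, so the FWHM of the positive lobe is reported).
#'
#' @inheritParams dog
#' @return FWHM in degrees (positive; `NA` if `amplitude == 0`).
#' @export
dog_fwhm <- function(amplitude, width) {
  if (amplitude == 0) return(NA_real_)
  xpk <- 1 / (width * sqrt(2))
  half <- function(x) dog(x, amplitude, width) / amplitude - 0.5
  lo <- stats::uniroot(half, interval = c(1e-9, xpk), tol = 1e-10)$root
  # beyond the peak the curve decays to 0, so a half crossing always exists
  hi <- stats::uniroot(half, interval = c(xpk, xpk * 40), tol = 1e-10)$root
  hi - lo
}
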