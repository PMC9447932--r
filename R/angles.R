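#' Wrap orientation differences to (-90, 90]
#'
#' Orientations are 180-degree periodic, so the signed difference between two
#' orientations is only defined up to 180 degrees. All angle arithmetic in this
#' package maps orientations onto the full circle by doubling (orientation x 2
#' in radians), operates there, and halves back. `wrap_ori()` is the scalar
#' version of that convention: it reduces any signed orientation difference to
#' the principal interval (-90, 90].
#'
#' @param x Numeric vector of orientation differences in degrees.
#' @return Numeric vector in (-90, 90].
#' @examples
#' wrap_ori(c(0, 90, 91, 180, -135))
#' @export
wrap_ori <- function(x) {
  out <- ((x + 90) %% 180) - 90
  # %% puts the boundary at -90; the convention keeps +90 instead
  out[out == -90] <- 90
  out
}

#' @keywords internal
#' @noRd
deg2rad2 <- function(theta) theta * pi / 90  # doubled-angle radians

#' Circular mean of orientation errors
#'
#' Computes the mean resultant vector of 180-degree periodic angles in the
#' doubled-angle space and reports its angle back in orientation degrees.
#'
#' @param x Orientation angles or errors in degrees.
#' @param na.rm Drop missing values first?
#' @return Mean direction in degrees, in (-90, 90].
#' @seealso [circ_sd_deg()], [circ_corr_deg()]
#' @export
circ_mean_deg <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  z <- mean(exp(1i * deg2rad2(x)))
  wrap_ori(Arg(z) * 90 / pi)
}

#' Circular standard deviation of orientation errors
#'
#' Standard circular SD, `sqrt(-2 log |R|)` where `R` is the mean resultant
#' length in doubled-angle space. Unitless; 0 when all angles coincide and
#' unbounded as the distribution approaches uniform. For small dispersions it
#' approximates the SD of the doubled angles in radians.
#'
#' @inheritParams circ_mean_deg
#' @return Nonnegative scalar (unitless).
#' @export
circ_sd_deg <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  r <- Mod(mean(exp(1i * deg2rad2(x))))
  sqrt(-2 * log(pmin(pmax(r, .Machine$double.xmin), 1)))
}

#' Circular correlation between two sets of orientations
#'
#' Fisher-Lee T-linear circular correlation computed in doubled-angle space,
#' in its pairwise form
#' \deqn{r = \frac{\sum_{i<j} \sin(a_i - a_j)\sin(b_i - b_j)}
#'   {\sqrt{\sum_{i<j}\sin^2(a_i - a_j)\sum_{i<j}\sin^2(b_i - b_j)}},}
#' which does not reference circular means and therefore stays well defined
#' when the marginals are uniform over the circle (as presented and decoded
#' orientations are). Used to index decoding performance.
#'
#' @param a,b Orientation vectors in degrees (same length, n >= 2).
#' @return Correlation in `[-1, 1]`.
#' @export
circ_corr_deg <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- as.vector(a)[keep]; b <- as.vector(b)[keep]
  if (length(a) < 2) {
    rlang::abort("circular correlation needs at least 2 paired angles",
                 class = "serialdep_error_n")
  }
  aa <- deg2rad2(a); bb <- deg2rad2(b)
  sa <- sin(outer(aa, aa, `-`))
  sb <- sin(outer(bb, bb, `-`))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(0)
  sum(sa * sb) / den
}
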