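#' Construct a von Mises population encoding model
#'
#' The encoding stage consists of `n_neurons` units with von Mises tuning
#' curves evenly tiling the 180-degree orientation space (doubled-angle
#' convention). The expected unadapted response of neuron i to stimulus
#' theta is `rate * exp(kappa * (cos(phi_i - theta) - 1))`, so the peak
#' unadapted rate equals `rate`.
#'
#' @param n_neurons Number of units tiling `[0, 180)` (default 100).
#' @param kappa Tuning concentration (dimensionless, default 1).
#' @param rate Mean-rate scale `R`; the peak expected Poisson rate. Has no
#'   effect on the bias of non-Bayesian decoders and is conventionally fixed
#'   at 5 for them; it sharpens the likelihood relative to the prior for
#'   Bayesian decoders.
#' @return An object of class `pop_model` with fields `phi` (tuning centers,
#'   degrees), `kappa` and `rate`.
#' @examples
#' m <- pop_model()
#' range(pop_response(m, theta = 45))
#' @export
pop_model <- function(n_neurons = 100, kappa = 1, rate = 5) {
  stopifnot(n_neurons >= 2, kappa > 0, rate > 0)
  structure(
    list(phi = seq(0, 180, length.out = n_neurons + 1)[-(n_neurons + 1)],
         kappa = kappa, rate = rate),
    class = "pop_model"
  )
}

#' @export
print.pop_model <- function(x, ...) {
  cat(sprintf("<pop_model> %d von Mises units, kappa = %g, rate = %g\n",
              length(x$phi), x$kappa, x$rate))
  invisible(x)
}

#' Adaptation gain profile across the population
#'
#' Gain is dipped around the previous stimulus by a rectified cubed cosine:
#' `gamma_i = 1 - rect(gamma_m * cos^3(gamma_s * (phi_i - theta_prev)))`,
#' with the cosine argument in doubled-angle space. `gamma_m` sets the depth
#' of the dip (gain at the adapter is `1 - gamma_m`), `gamma_s` scales its
#' width (larger = narrower dip). Gains are 1 wherever the rectified lobe
#' vanishes, so they always lie in `[1 - gamma_m, 1]`.
#'
#' @param model A [pop_model()].
#' @param theta_prev Previous stimulus orientation, degrees.
#' @param gamma_m Adaptation magnitude in `[0, 1]`.
#' @param gamma_s Adaptation width scale (> 0).
#' @return Gain vector of length `n_neurons`.
#' @export
gain_profile <- function(model, theta_prev, gamma_m, gamma_s = 1) {
  if (gamma_m < 0 || gamma_m > 1) {
    rlang::abort("`gamma_m` must lie in [0, 1]", class = "serialdep_error_gain")
  }
  if (gamma_s <= 0) {
    rlang::abort("`gamma_s` must be positive", class = "serialdep_error_gain")
  }
  # the dip is centered on the adapter: scale the principal (wrapped)
  # orientation difference, not the raw one, so gamma_s != 1 keeps the
  # profile single-valued on the orientation circle
  d <- wrap_ori(model$phi - theta_prev)
  lobe <- gamma_m * cos(gamma_s * deg2rad2(d))^3
  1 - pmax(0, lobe)
}

#' Expected population response to a stimulus
#'
#' Unadapted expected rates, optionally scaled by the adaptation gain
#' profile keyed to the previous stimulus.
#'
#' @inheritParams gain_profile
#' @param theta Current stimulus orientation, degrees.
#' @param theta_prev Previous stimulus, degrees, or `NULL` for no adaptation.
#' @return Expected-rate vector (length `n_neurons`), all values >= 0.
#' @export
pop_response <- function(model, theta, theta_prev = NULL, gamma_m = 0,
                         gamma_s = 1) {
  tun <- exp(model$kappa * (cos(deg2rad2(model$phi - theta)) - 1))
  g <- if (is.null(theta_prev)) 1 else gain_profile(model, theta_prev, gamma_m, gamma_s)
  model$rate * g * tun
}

#' @keywords internal
#' @noRd
ori_grid <- function(step = 1) seq(0, 180 - step, by = step)

# Unadapted expected-rate matrix over an orientation grid (grid x neurons).
#' @keywords internal
#' @noRd
rate_matrix <- function(model, grid = ori_grid()) {
  d <- outer(grid, model$phi, function(g, p) cos(deg2rad2(p - g)))
  model$rate * exp(model$kappa * (d - 1))
}

# Poisson log-likelihood profile over the grid. `resp` may be non-integer
# (noiseless expected rates are used as observations during fitting); the
# continuous extension k*log(lambda) - lambda - lgamma(k+1) is used, with a
# rate floor to keep the log finite where rectification could zero a rate.
#' @keywords internal
#' @noRd
poisson_loglik <- function(resp, lambda_mat, floor = 1e-12) {
  lam <- pmax(lambda_mat, floor)
  drop(log(lam) %*% resp) - rowSums(lam) - sum(lgamma(resp + 1))
}

# Parabolic refinement of a circular-grid argmax. Returns the interpolated
# abscissa in degrees on the 180-periodic orientation circle.
#' @keywords internal
#' @noRd
peak_interp <- function(grid, values, interp = TRUE) {
  i <- which.max(values)
  if (!interp || length(values) < 3) return(grid[i])
  n <- length(values)
  im <- if (i == 1) n else i - 1
  ip <- if (i == n) 1 else i + 1
  step <- 180 / n
  den <- values[im] - 2 * values[i] + values[ip]
  off <- if (den == 0) 0 else 0.5 * (values[im] - values[ip]) / den
  off <- max(min(off, 0.5), -0.5)
  (grid[i] + off * step) %% 180
}

#' Decode a population response into a likelihood profile
#'
#' Evaluates the log-likelihood of each orientation on a grid under a Poisson
#' observation model, using expected rates that encode one of three
#' assumptions about adaptation, optionally multiplied by a temporal
#' contiguity prior:
#' \describe{
#'   \item{`unaware`}{expected rates are the unadapted profile; the readout
#'     is repelled from the previous stimulus when the input was adapted.}
#'   \item{`aware`}{expected rates use the true adaptation `(gamma_m,
#'     gamma_s)`; on noiseless adapted input the MAP equals the presented
#'     orientation.}
#'   \item{`overaware`}{expected rates use an assumed pair `(gamma_m2,
#'     gamma_s2)`; exaggerating adaptation yields net attraction.}
#'   \item{`bayes_unaware`, `bayes_aware`}{the corresponding likelihood is
#'     multiplied by a mixture prior centered on the previous stimulus
#'     (see [contiguity_prior()]).}
#' }
#'
#' @param resp Observed (or expected, for noiseless decoding) response vector,
#'   length `n_neurons`; nonnegative.
#' @param model A [pop_model()].
#' @param decoder One of `"unaware"`, `"aware"`, `"overaware"`,
#'   `"bayes_unaware"`, `"bayes_aware"`.
#' @param theta_prev Previous stimulus, degrees. Required by every decoder
#'   except `"unaware"`.
#' @param gamma_m,gamma_s True adaptation parameters (used by `aware` /
#'   `bayes_aware`).
#' @param gamma_m2,gamma_s2 Assumed adaptation (used by `overaware`).
#' @param p_same,psi Prior mixture weight and transition width in degrees
#'   (Bayesian decoders).
#' @param grid_step Grid resolution in degrees (default 1).
#' @param interp Parabolically refine the MAP between grid points?
#' @return A `likelihood_profile`: tibble with columns `theta`, `loglik`,
#'   `posterior` (normalized to sum to 1), plus attributes `map` (decoded
#'   orientation, degrees) and `decoder`.
#' @export
decode_profile <- function(resp, model, decoder = "unaware", theta_prev = NULL,
                           gamma_m = 0, gamma_s = 1,
                           gamma_m2 = gamma_m, gamma_s2 = gamma_s,
                           p_same = 0.64, psi = 20,
                           grid_step = 1, interp = TRUE) {
  decoder <- match.arg(decoder, c("unaware", "aware", "overaware",
                                  "bayes_unaware", "bayes_aware"))
  if (any(resp < 0)) {
    rlang::abort("`resp` must be nonnegative", class = "serialdep_error_resp")
  }
  if (decoder != "unaware" && is.null(theta_prev)) {
    rlang::abort(paste0("decoder '", decoder, "' requires `theta_prev`"),
                 class = "serialdep_error_prev")
  }
  grid <- ori_grid(grid_step)
  lam <- rate_matrix(model, grid)
  gain <- switch(decoder,
    unaware = , bayes_unaware = NULL,
    aware = , bayes_aware = gain_profile(model, theta_prev, gamma_m, gamma_s),
    overaware = gain_profile(model, theta_prev, gamma_m2, gamma_s2))
  if (!is.null(gain)) lam <- sweep(lam, 2, gain, `*`)
  ll <- poisson_loglik(resp, lam)
  score <- ll
  if (decoder %in% c("bayes_unaware", "bayes_aware")) {
    score <- ll + log(contiguity_prior(grid, theta_prev, p_same, psi))
  }
  post <- exp(score - max(score))
  post <- post / sum(post)
  out <- tibble::tibble(theta = grid, loglik = ll, posterior = post)
  structure(out, map = peak_interp(grid, score, interp), decoder = decoder,
            class = c("likelihood_profile", class(out)))
}

#' Temporal contiguity prior over orientation
#'
#' Mixture of a circular Gaussian centered on the previous stimulus and a
#' uniform component: `p_same * N_circ(theta; theta_prev, psi) +
#' (1 - p_same) * uniform`, discretized on the orientation grid and
#' normalized to sum to 1. The circular Gaussian uses the wrapped orientation
#' difference in degrees.
#'
#' @param grid Orientation grid, degrees.
#' @param theta_prev Previous stimulus, degrees.
#' @param p_same Mixture weight of the contiguity component (default 0.64).
#' @param psi Transition width in degrees.
#' @return Probability vector over `grid` (sums to 1).
#' @export
contiguity_prior <- function(grid, theta_prev, p_same = 0.64, psi = 20) {
  stopifnot(p_same >= 0, p_same <= 1, psi > 0)
  d <- wrap_ori(grid - theta_prev)
  g <- exp(-d^2 / (2 * psi^2))
  g <- g / sum(g)
  p <- p_same * g + (1 - p_same) / length(grid)
  p / sum(p)
}

#' Decoded orientation (MAP) of a likelihood profile
#' @param profile A `likelihood_profile` from [decode_profile()].
#' @return Orientation in degrees.
#' @export
profile_map <- function(profile) attr(profile, "map")
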