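#' Noiseless bias curve of a decoder
#'
#' For each orientation difference `delta = theta_prev - theta_n`, encodes the
#' current stimulus through the adapted population (no noise), decodes with
#' the requested readout, and reports the signed decoding error in degrees.
#' Positive values are attraction toward the previous stimulus, negative
#' repulsion. By construction every curve is odd-symmetric with zeros at 0
#' and +/-90 degrees; the `aware` readout is identically zero.
#'
#' @inheritParams decode_profile
#' @param delta Grid of orientation differences in degrees (default 1-degree
#'   steps over `[-90, 90]`).
#' @return A tibble of class `bias_curve` with columns `delta` and `bias`
#'   (degrees).
#' @examples
#' m <- pop_model()
#' head(model_bias_curve(m, "unaware", gamma_m = 0.3))
#' @export
model_bias_curve <- function(model, decoder = "unaware",
                             delta = seq(-90, 90, by = 1),
                             gamma_m = 0, gamma_s = 1,
                             gamma_m2 = gamma_m, gamma_s2 = gamma_s,
                             p_same = 0.64, psi = 20,
                             grid_step = 1, interp = TRUE) {
  decoder <- match.arg(decoder, c("unaware", "aware", "overaware",
                                  "bayes_unaware", "bayes_aware"))
  eng <- bias_engine(model, decoder, gamma_m, gamma_s, gamma_m2, gamma_s2,
                     p_same, psi, grid_step, interp)
  out <- tibble::tibble(delta = delta, bias = vapply(delta, eng, numeric(1)))
  class(out) <- c("bias_curve", class(out))
  attr(out, "decoder") <- decoder
  out
}

# Returns a closure delta -> noiseless decoded bias (degrees). The unadapted
# rate matrix, its log and row sums are hoisted out so repeated calls during
# grid-search fitting cost two matrix-vector products each.
#' @keywords internal
#' @noRd
bias_engine <- function(model, decoder, gamma_m, gamma_s,
                        gamma_m2 = gamma_m, gamma_s2 = gamma_s,
                        p_same = 0.64, psi = 20, grid_step = 1,
                        interp = TRUE) {
  grid <- ori_grid(grid_step)
  U <- rate_matrix(model, grid)
  logU <- log(pmax(U, 1e-12))
  rsU <- rowSums(U)
  tun0 <- U[1, ]  # unadapted response to theta_n = 0
  aware_pair <- switch(decoder,
    aware = , bayes_aware = c(gamma_m, gamma_s),
    overaware = c(gamma_m2, gamma_s2),
    NULL)
  function(delta) {
    k <- gain_profile(model, delta, gamma_m, gamma_s) * tun0
    if (is.null(aware_pair)) {
      score <- drop(logU %*% k) - rsU
    } else {
      g2 <- pmax(gain_profile(model, delta, aware_pair[1], aware_pair[2]), 1e-12)
      score <- drop(logU %*% k) + sum(k * log(g2)) - drop(U %*% g2)
    }
    if (decoder %in% c("bayes_unaware", "bayes_aware")) {
      score <- score + log(contiguity_prior(grid, delta, p_same, psi))
    }
    wrap_ori(peak_interp(grid, score, interp))
  }
}

#' Simulate decoding under Poisson response variability
#'
#' Draws trials with random current/previous orientations, samples Poisson
#' spike counts from the adapted population, decodes each trial with the
#' requested readout, and returns the per-trial decoding errors. Used to
#' study how decoder variance depends on the distance to the previous
#' stimulus (the close/far variance signature of gain adaptation).
#'
#' @inheritParams model_bias_curve
#' @param n_trials Number of simulated trials (default 1000).
#' @param seed Integer seed.
#' @return Tibble with columns `theta`, `theta_prev`, `delta`, `decoded`,
#'   `error` (degrees).
#' @export
sim_decoder_errors <- function(model, decoder = "unaware", n_trials = 1000,
                               gamma_m = 0, gamma_s = 1,
                               gamma_m2 = gamma_m, gamma_s2 = gamma_s,
                               p_same = 0.64, psi = 20,
                               grid_step = 1, seed = 1) {
  decoder <- match.arg(decoder, c("unaware", "aware", "overaware",
                                  "bayes_unaware", "bayes_aware"))
  stopifnot(n_trials >= 1)
  set.seed(seed)
  grid <- ori_grid(grid_step)
  U <- rate_matrix(model, grid)
  logU <- log(pmax(U, 1e-12))
  rsU <- rowSums(U)
  theta <- stats::runif(n_trials, 0, 180)
  delta <- stats::runif(n_trials, -90, 90)
  theta_prev <- (theta + delta) %% 180
  aware_pair <- switch(decoder,
    aware = , bayes_aware = c(gamma_m, gamma_s),
    overaware = c(gamma_m2, gamma_s2),
    NULL)
  decoded <- vapply(seq_len(n_trials), function(t) {
    mu <- pop_response(model, theta[t], theta_prev[t], gamma_m, gamma_s)
    k <- stats::rpois(length(mu), mu)
    if (is.null(aware_pair)) {
      score <- drop(logU %*% k) - rsU
    } else {
      g2 <- pmax(gain_profile(model, theta_prev[t], aware_pair[1], aware_pair[2]),
                 1e-12)
      score <- drop(logU %*% k) + sum(k * log(g2)) - drop(U %*% g2)
    }
    if (decoder %in% c("bayes_unaware", "bayes_aware")) {
      score <- score + log(contiguity_prior(grid, theta_prev[t], p_same, psi))
    }
    peak_interp(grid, score, interp = TRUE)
  }, numeric(1))
  tibble::tibble(theta = theta, theta_prev = theta_prev, delta = delta,
                 decoded = decoded, error = wrap_ori(decoded - theta))
}
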