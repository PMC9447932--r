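# Two-stage fitting of the encoder-decoder model:
#   stage 1 (encoding): (gamma_m, gamma_s) by RSS against neural decoding
#     errors, using the noiseless unaware bias curve;
#   stage 2 (readout): the decoder's 2 free parameters by maximum likelihood
#     of binary responses, with the trial bias given by the decoder's
#     noiseless bias curve and a fixed guess rate.
# Both stages use a dense grid (30 x 30) followed by Nelder-Mead refinement
# around the best grid point, and share cross-validation folds.

# Odd-symmetric interpolation of a half-curve (computed on delta >= 0) onto
# arbitrary per-trial deltas.
#' @keywords internal
#' @noRd
interp_odd <- function(delta_fit, curve, delta) {
  sign(delta) * stats::approx(delta_fit, curve, xout = abs(delta),
                              rule = 2)$y
}

# delta -> unaware bias vector as a function of encoding parameters, with
# the unadapted rate matrix hoisted out of the parameter loop.
#' @keywords internal
#' @noRd
make_unaware_engine <- function(model, grid_step = 1) {
  grid <- ori_grid(grid_step)
  U <- rate_matrix(model, grid)
  logU <- log(pmax(U, 1e-12))
  rsU <- rowSums(U)
  tun0 <- U[1, ]
  phi <- model$phi
  function(gm, gs, deltas) {
    vapply(deltas, function(d) {
      k <- (1 - pmax(0, gm * cos(gs * deg2rad2(wrap_ori(phi - d)))^3)) * tun0
      wrap_ori(peak_interp(grid, drop(logU %*% k) - rsU, TRUE))
    }, numeric(1))
  }
}

#' @keywords internal
#' @noRd
refine_nm <- function(obj, start, lower, upper) {
  clamped <- function(p) obj(pmin(pmax(p, lower), upper))
  nm <- stats::optim(start, clamped, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-8))
  list(par = pmin(pmax(nm$par, lower), upper), value = nm$value)
}

#' Fit the encoding stage to neural decoding errors
#'
#' Finds the adaptation parameters `(gamma_m, gamma_s)` whose noiseless
#' unaware-decoder bias curve best matches observed decoding errors, by
#' minimizing the residual sum of squares. A 30 x 30 grid over
#' `gamma_m in [0, 0.8]`, `gamma_s in [0.25, 4]` is searched first, then the
#' best grid point is refined with Nelder-Mead; the refined objective is
#' never worse than the best grid point. With fold labels, one parameter
#' pair is fit per fold on that fold's training trials (the same groups as
#' the neural decoder).
#'
#' @param errors Signed decoding errors, degrees.
#' @param delta Orientation difference to the previous stimulus, degrees.
#' @param model A [pop_model()].
#' @param folds Optional fold labels (one per trial); `NULL` fits once on
#'   all trials.
#' @param grid_n Grid points per parameter (default 30).
#' @param gamma_m_range,gamma_s_range Search ranges.
#' @param delta_step Spacing of the internal bias-curve grid, degrees.
#' @return An `encoding_fit`: tibble with one row per fold (`fold`,
#'   `gamma_m`, `gamma_s`, `rss`), with the model and grid stored as
#'   attributes.
#' @export
fit_encoding <- function(errors, delta, model, folds = NULL, grid_n = 30,
                         gamma_m_range = c(0, 0.8),
                         gamma_s_range = c(0.25, 4), delta_step = 2) {
  keep <- !is.na(errors) & !is.na(delta)
  errors <- errors[keep]
  delta <- delta[keep]
  folds <- if (is.null(folds)) rep(1L, length(errors)) else folds[keep]
  engine <- make_unaware_engine(model)
  delta_fit <- seq(0, 90, by = delta_step)
  gm_grid <- seq(gamma_m_range[1], gamma_m_range[2], length.out = grid_n)
  gs_grid <- seq(gamma_s_range[1], gamma_s_range[2], length.out = grid_n)
  fit_one <- function(e, d) {
    obj <- function(p) {
      pred <- interp_odd(delta_fit, engine(p[1], p[2], delta_fit), d)
      sum((e - pred)^2)
    }
    grid_val <- outer(seq_along(gm_grid), seq_along(gs_grid),
                      Vectorize(function(i, j) obj(c(gm_grid[i], gs_grid[j]))))
    best <- arrayInd(which.min(grid_val), dim(grid_val))
    start <- c(gm_grid[best[1]], gs_grid[best[2]])
    ref <- refine_nm(obj, start, c(gamma_m_range[1], gamma_s_range[1]),
                     c(gamma_m_range[2], gamma_s_range[2]))
    if (ref$value <= min(grid_val)) ref else
      list(par = start, value = min(grid_val))
  }
  fold_ids <- sort(unique(folds))
  out <- purrr::map_dfr(fold_ids, function(f) {
    tr <- if (length(fold_ids) == 1) folds == f else folds != f
    r <- fit_one(errors[tr], delta[tr])
    tibble::tibble(fold = f, gamma_m = r$par[1], gamma_s = r$par[2],
                   rss = r$value)
  })
  structure(out, model = model, stage = "encoding",
            class = c("encoding_fit", class(out)))
}

# Per-delta noiseless bias predictions for the three behavioral readouts,
# parameterized by the decoder's two free parameters. Expensive shared
# pieces (rate matrix, adapted responses, base log-likelihoods) are hoisted.
#' @keywords internal
#' @noRd
make_readout_engine <- function(model, decoder, gamma_m, gamma_s, delta_fit,
                                grid_step = 1) {
  grid <- ori_grid(grid_step)
  U <- rate_matrix(model, grid)
  logU <- log(pmax(U, 1e-12))
  rsU <- rowSums(U)
  tun0 <- U[1, ]
  K <- vapply(delta_fit,
              function(d) gain_profile(model, d, gamma_m, gamma_s) * tun0,
              numeric(length(tun0)))
  T1 <- logU %*% K  # grid x delta
  map_cols <- function(score) {
    vapply(seq_along(delta_fit),
           function(j) wrap_ori(peak_interp(grid, score[, j], TRUE)),
           numeric(1))
  }
  if (decoder == "overaware") {
    function(par) {  # par = (gamma_m2, gamma_s2)
      G2 <- vapply(delta_fit,
                   function(d) pmax(gain_profile(model, d, par[1], par[2]), 1e-12),
                   numeric(length(tun0)))
      score <- T1 + rep(colSums(K * log(G2)), each = nrow(T1)) - U %*% G2
      map_cols(score)
    }
  } else {
    base <- if (decoder == "bayes_unaware") {
      sweep(T1, 1, rsU)
    } else {  # bayes_aware likelihood
      G <- vapply(delta_fit,
                  function(d) pmax(gain_profile(model, d, gamma_m, gamma_s), 1e-12),
                  numeric(length(tun0)))
      T1 + rep(colSums(K * log(G)), each = nrow(T1)) - U %*% G
    }
    R0 <- model$rate
    function(par) {  # par = (R, psi)
      lp <- vapply(delta_fit,
                   function(d) log(contiguity_prior(grid, d, psi = par[2])),
                   numeric(length(grid)))
      map_cols((par[1] / R0) * base + lp)
    }
  }
}

#' Fit a readout scheme to binary behavioral responses
#'
#' Second stage of the encoder-decoder fit: given encoding parameters (from
#' [fit_encoding()] or supplied directly), finds the readout's two free
#' parameters maximizing the likelihood of CW/CCW responses, with the trial
#' bias `mu(delta)` given by the readout's noiseless bias curve, the
#' response SD fixed at a per-observer estimate, and a fixed guess rate.
#' Free parameters are `(R, psi)` for the Bayesian readouts (rate scale and
#' prior transition width; `p_same` fixed at 0.64) and
#' `(gamma_m2, gamma_s2)` for the overaware readout (`R` stays at the
#' model's fixed rate, which does not affect non-Bayesian bias). Dense grid
#' search (30 per parameter, `R` log-spaced) precedes Nelder-Mead
#' refinement; fits are per cross-validation fold on training trials, with
#' the held-out negative log-likelihood reported.
#'
#' @param data Trial data frame with `delta`, `probe_offset`, `response`.
#' @param encoding An `encoding_fit`, or `c(gamma_m, gamma_s)`.
#' @param model A [pop_model()]; defaults to the one stored in `encoding`.
#' @param decoder `"bayes_unaware"`, `"bayes_aware"` or `"overaware"`.
#' @param sigma Response SD in degrees; `NULL` estimates it once from all
#'   trials with [fit_psychometric()] (bias free as a single constant).
#' @param folds Optional fold labels (must match the encoding fit's folds
#'   when `encoding` is an `encoding_fit` with several folds).
#' @param guess_rate Fixed guess rate (default 0.25).
#' @param grid_n Grid points per parameter.
#' @param r_range,psi_range,gamma_m2_range,gamma_s2_range Search ranges.
#' @param delta_step Spacing of the internal bias-curve grid, degrees.
#' @return A `readout_fit`: tibble with one row per fold (`fold`, `par1`,
#'   `par2`, `nll_train`, `nll_test`), with decoder name, parameter names,
#'   encoding parameters and `sigma` stored as attributes.
#' @export
fit_readout <- function(data, encoding, model = NULL,
                        decoder = c("bayes_unaware", "bayes_aware", "overaware"),
                        sigma = NULL, folds = NULL, guess_rate = 0.25,
                        grid_n = 30, r_range = c(0.5, 50),
                        psi_range = c(2, 60), gamma_m2_range = c(0, 0.8),
                        gamma_s2_range = c(0.25, 4), delta_step = 2) {
  decoder <- match.arg(decoder)
  if (inherits(encoding, "encoding_fit")) {
    if (is.null(model)) model <- attr(encoding, "model")
    enc_tab <- encoding
  } else {
    if (is.null(model)) {
      rlang::abort("`model` is required when `encoding` is a parameter pair",
                   class = "serialdep_error_args")
    }
    enc_tab <- tibble::tibble(fold = 1L, gamma_m = encoding[1],
                              gamma_s = encoding[2])
  }
  cw <- response_to_cw(data$response)
  keep <- !is.na(cw) & !is.na(data$probe_offset) & !is.na(data$delta)
  cw <- cw[keep]
  x <- data$probe_offset[keep]
  d <- data$delta[keep]
  folds <- if (is.null(folds)) rep(1L, length(cw)) else folds[keep]
  fold_ids <- sort(unique(folds))
  if (nrow(enc_tab) > 1 && !identical(sort(enc_tab$fold), fold_ids)) {
    rlang::abort("encoding and readout fold labels do not match",
                 class = "serialdep_error_folds")
  }
  if (is.null(sigma)) sigma <- fit_psychometric(data[keep, ], guess_rate = guess_rate)$sigma
  delta_fit <- seq(0, 90, by = delta_step)
  if (decoder == "overaware") {
    g1 <- seq(gamma_m2_range[1], gamma_m2_range[2], length.out = grid_n)
    g2 <- seq(gamma_s2_range[1], gamma_s2_range[2], length.out = grid_n)
    lower <- c(gamma_m2_range[1], gamma_s2_range[1])
    upper <- c(gamma_m2_range[2], gamma_s2_range[2])
    par_names <- c("gamma_m2", "gamma_s2")
  } else {
    g1 <- exp(seq(log(r_range[1]), log(r_range[2]), length.out = grid_n))
    g2 <- seq(psi_range[1], psi_range[2], length.out = grid_n)
    lower <- c(r_range[1], psi_range[1])
    upper <- c(r_range[2], psi_range[2])
    par_names <- c("rate", "psi")
  }
  nll_of <- function(curve, idx) {
    mu <- interp_odd(delta_fit, curve, d[idx])
    binom_nll(response_prob(x[idx], mu, sigma, guess_rate), cw[idx])
  }
  out <- purrr::map_dfr(fold_ids, function(f) {
    tr_idx <- if (length(fold_ids) == 1) which(folds == f) else which(folds != f)
    te_idx <- which(folds == f)
    enc <- if (nrow(enc_tab) > 1) enc_tab[enc_tab$fold == f, ] else enc_tab[1, ]
    engine <- make_readout_engine(model, decoder, enc$gamma_m, enc$gamma_s,
                                  delta_fit)
    obj <- function(p) nll_of(engine(p), tr_idx)
    grid_val <- outer(seq_along(g1), seq_along(g2),
                      Vectorize(function(i, j) obj(c(g1[i], g2[j]))))
    best <- arrayInd(which.min(grid_val), dim(grid_val))
    start <- c(g1[best[1]], g2[best[2]])
    ref <- refine_nm(obj, start, lower, upper)
    if (ref$value > min(grid_val)) {
      ref <- list(par = start, value = min(grid_val))
    }
    tibble::tibble(fold = f, par1 = ref$par[1], par2 = ref$par[2],
                   nll_train = ref$value,
                   nll_test = nll_of(engine(ref$par), te_idx))
  })
  names(out)[names(out) == "par1"] <- par_names[1]
  names(out)[names(out) == "par2"] <- par_names[2]
  structure(out, model = model, decoder = decoder, par_names = par_names,
            encoding = enc_tab, sigma = sigma, guess_rate = guess_rate,
            stage = "readout", class = c("readout_fit", class(out)))
}

#' Compare fitted readout schemes by held-out likelihood
#'
#' Pools the out-of-fold log-likelihood of the observed responses across
#' folds for each fitted readout. No information criterion is applied: all
#' readouts have the same number of free parameters by design.
#'
#' @param ... Named `readout_fit` objects fitted on identical folds.
#' @return Tibble with `decoder`, `loglik` (pooled held-out, nats), `n_folds`.
#' @export
compare_readouts <- function(...) {
  fits <- list(...)
  if (length(fits) < 2) {
    rlang::abort("need at least 2 fitted readouts", class = "serialdep_error_args")
  }
  fold_sets <- lapply(fits, function(f) sort(f$fold))
  if (!all(vapply(fold_sets, identical, logical(1), fold_sets[[1]]))) {
    rlang::abort("readouts were fitted on different folds",
                 class = "serialdep_error_folds")
  }
  purrr::map_dfr(fits, function(f) {
    tibble::tibble(decoder = attr(f, "decoder"),
                   loglik = -sum(f$nll_test), n_folds = nrow(f))
  })
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' `0.5 KL(p || m) + 0.5 KL(q || m)` with `m = (p + q)/2`, in nats; bounded
#' by `log(2)`, and 0 for identical distributions.
#'
#' @param p,q Probability vectors on the same support (renormalized).
#' @return Divergence in nats.
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Jensen-Shannon divergence between two error samples
#'
#' Discretizes both samples of wrapped orientation errors on a common
#' binning of `(-90, 90]` with additive smoothing of empty bins, then
#' applies [js_divergence()].
#'
#' @param a,b Error samples, degrees.
#' @param bin_width Bin width in degrees (default 4).
#' @param eps Smoothing mass added to every bin (default 1e-6).
#' @return Divergence in nats.
#' @export
error_js <- function(a, b, bin_width = 4, eps = 1e-6) {
  brk <- seq(-90, 90, by = bin_width)
  h <- function(x) {
    cnt <- graphics::hist(wrap_ori(x), breaks = brk, plot = FALSE)$counts
    cnt + eps
  }
  js_divergence(h(a), h(b))
}

#' Simulate response variability of fitted readouts
#'
#' For each cross-validation fold's fitted parameters, simulates `n_sim`
#' trials with Poisson-sampled population activity decoded by the fitted
#' readout, pools the decoded errors, and summarizes their dispersion
#' following close versus far previous stimuli (circular SD). If reference
#' errors are supplied, the Jensen-Shannon divergence between the pooled
#' simulated error distribution and the reference is reported.
#'
#' @param fit A `readout_fit` (or `encoding_fit`, simulated with the unaware
#'   readout).
#' @param n_sim Simulated trials per fold (default 1000).
#' @param seed Integer seed.
#' @param reference Optional vector of reference errors, degrees.
#' @param close_thresh Close/far split on `|delta|` (default 30).
#' @return List with `errors` (pooled tibble from [sim_decoder_errors()]),
#'   and `summary` (tibble: `sigma_close`, `sigma_far`, `js`).
#' @export
readout_variance <- function(fit, n_sim = 1000, seed = 1, reference = NULL,
                             close_thresh = 30) {
  model <- attr(fit, "model")
  is_enc <- inherits(fit, "encoding_fit")
  errs <- purrr::map_dfr(seq_len(nrow(fit)), function(i) {
    if (is_enc) {
      sim_decoder_errors(model, "unaware", n_trials = n_sim,
                         gamma_m = fit$gamma_m[i], gamma_s = fit$gamma_s[i],
                         seed = seed + i)
    } else {
      enc <- attr(fit, "encoding")
      er <- if (nrow(enc) > 1) enc[enc$fold == fit$fold[i], ] else enc[1, ]
      dec <- attr(fit, "decoder")
      pn <- attr(fit, "par_names")
      if (dec == "overaware") {
        sim_decoder_errors(model, "overaware", n_trials = n_sim,
                           gamma_m = er$gamma_m, gamma_s = er$gamma_s,
                           gamma_m2 = fit[[pn[1]]][i], gamma_s2 = fit[[pn[2]]][i],
                           seed = seed + i)
      } else {
        m2 <- pop_model(length(model$phi), model$kappa, rate = fit[[pn[1]]][i])
        sim_decoder_errors(m2, dec, n_trials = n_sim,
                           gamma_m = er$gamma_m, gamma_s = er$gamma_s,
                           psi = fit[[pn[2]]][i], seed = seed + i)
      }
    }
  })
  close <- abs(errs$delta) < close_thresh
  summary <- tibble::tibble(
    sigma_close = circ_sd_deg(errs$error[close]),
    sigma_far = circ_sd_deg(errs$error[!close]),
    js = if (is.null(reference)) NA_real_ else error_js(errs$error, reference))
  list(errors = errs, summary = summary)
}
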