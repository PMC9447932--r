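#' Probability of a clockwise response
#'
#' Binary-response model for the discrimination task: encoding is a Gaussian
#' centered on the remembered stimulus with bias `mu` and SD `sigma`, and a
#' fixed guess rate is mixed in so no response ever has zero likelihood:
#' `P(CW) = guess_rate/2 + (1 - guess_rate) * pnorm((delta_probe - mu)/sigma)`.
#' The probability is therefore bounded in
#' `[guess_rate/2, 1 - guess_rate/2]`.
#'
#' @param delta_probe Signed probe offset in degrees (positive = probe CW of
#'   the stimulus).
#' @param mu Bias in degrees.
#' @param sigma Encoding SD in degrees (> 0).
#' @param guess_rate Fixed lapse probability (default 0.25).
#' @return Probability of a CW response.
#' @export
response_prob <- function(delta_probe, mu = 0, sigma = 5, guess_rate = 0.25) {
  stopifnot(sigma > 0, guess_rate >= 0, guess_rate < 1)
  guess_rate / 2 + (1 - guess_rate) * stats::pnorm((delta_probe - mu) / sigma)
}

#' @keywords internal
#' @noRd
response_to_cw <- function(response) {
  if (is.numeric(response)) return(as.numeric(response))
  out <- rep(NA_real_, length(response))
  out[tolower(response) %in% c("cw", "1")] <- 1
  out[tolower(response) %in% c("ccw", "0")] <- 0
  out
}

#' @keywords internal
#' @noRd
binom_nll <- function(p, cw) -sum(cw * log(p) + (1 - cw) * log1p(-p))

#' Fit the constant-bias response model
#'
#' Maximum-likelihood fit of bias `mu` and precision `sigma` to binary
#' CW/CCW responses at varying probe offsets, with the guess rate held
#' fixed (never estimated, so `sigma` is comparable across observers).
#' Optimized by bounded quasi-Newton (L-BFGS-B) from several `sigma` starts;
#' trials without a response are dropped and counted.
#'
#' @param data Data frame with columns `probe_offset` (degrees) and
#'   `response` (`"cw"`/`"ccw"`, or 1/0); `NA` responses are excluded.
#' @param mu Either `"free"` (default) or a fixed numeric bias.
#' @param guess_rate Fixed guess rate (default 0.25).
#' @param sigma_starts Starting values for `sigma`, degrees.
#' @return A `psychometric_fit` object with elements `mu`, `sigma`,
#'   `guess_rate`, `nll`, `n`, `n_dropped` and `boundary` (TRUE when all
#'   usable responses fell in one class).
#' @examples
#' d <- tibble::tibble(probe_offset = rep(c(-6, -2, 2, 6), each = 50))
#' d$response <- ifelse(stats::runif(200) < response_prob(d$probe_offset), "cw", "ccw")
#' fit_psychometric(d)
#' @export
fit_psychometric <- function(data, mu = "free", guess_rate = 0.25,
                             sigma_starts = c(2, 5, 10)) {
  cw <- response_to_cw(data$response)
  keep <- !is.na(cw) & !is.na(data$probe_offset)
  x <- data$probe_offset[keep]
  cw <- cw[keep]
  if (length(unique(x)) < 2) {
    rlang::abort("need responses at >= 2 distinct probe offsets",
                 class = "serialdep_error_support")
  }
  boundary <- length(unique(cw)) < 2
  mu_free <- identical(mu, "free")
  nll_fun <- function(par) {
    m <- if (mu_free) par[1] else mu
    s <- par[length(par)]
    binom_nll(response_prob(x, m, s, guess_rate), cw)
  }
  lower <- if (mu_free) c(-45, 0.1) else 0.1
  upper <- if (mu_free) c(45, 90) else 90
  fits <- lapply(sigma_starts, function(s0) {
    start <- if (mu_free) c(0, s0) else s0
    stats::optim(start, nll_fun, method = "L-BFGS-B",
                 lower = lower, upper = upper)
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  sigs <- vapply(fits, function(f) f$par[length(f$par)], numeric(1))
  best <- fits[[order(vals, sigs)[1]]]
  structure(
    list(mu = if (mu_free) best$par[1] else mu,
         sigma = best$par[length(best$par)],
         guess_rate = guess_rate, nll = best$value,
         n = length(cw), n_dropped = sum(!keep), boundary = boundary),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> mu = %.2f deg, sigma = %.2f deg (guess %.0f%%), NLL = %.2f, n = %d\n",
    x$mu, x$sigma, 100 * x$guess_rate, x$nll, x$n))
  invisible(x)
}

#' Fit a DoG serial-dependence curve to binary responses
#'
#' Maximum-likelihood fit of amplitude `A`, inverse-width `w` and precision
#' `sigma`, with the trial-wise bias given by `mu_t = dog(delta_t; A, w)`
#' inside the binary response model ([response_prob()]). Optimized from a
#' small multi-start grid with L-BFGS-B; ties broken by lowest NLL then
#' smallest `sigma`.
#'
#' @param data Data frame with columns `delta` (previous minus current
#'   orientation, degrees, in (-90, 90]), `probe_offset` and `response`.
#' @inheritParams fit_psychometric
#' @return A `dog_fit` object with `amplitude`, `width`, `sigma`, `fwhm`,
#'   `nll`, `n`, `method = "mle"`.
#' @export
fit_dog <- function(data, guess_rate = 0.25) {
  cw <- response_to_cw(data$response)
  keep <- !is.na(cw) & !is.na(data$probe_offset) & !is.na(data$delta)
  x <- data$probe_offset[keep]
  d <- data$delta[keep]
  cw <- cw[keep]
  if (length(unique(round(d))) < 4) {
    rlang::abort("degenerate `delta` support: need trials across several orientation differences",
                 class = "serialdep_error_support")
  }
  nll_fun <- function(par) {
    mu_t <- dog(d, par[1], par[2])
    binom_nll(response_prob(x, mu_t, par[3], guess_rate), cw)
  }
  starts <- expand.grid(A = c(-5, 0, 5), w = c(0.02, 0.05), s = c(3, 8))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(as.numeric(starts[i, ]), nll_fun, method = "L-BFGS-B",
                 lower = c(-45, 0.01, 0.1), upper = c(45, 0.3, 90))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  sigs <- vapply(fits, function(f) f$par[3], numeric(1))
  best <- fits[[order(vals, sigs)[1]]]
  structure(
    list(amplitude = best$par[1], width = best$par[2], sigma = best$par[3],
         fwhm = dog_fwhm(best$par[1], best$par[2]),
         nll = best$value, n = length(cw), method = "mle"),
    class = "dog_fit")
}

#' Least-squares DoG fit to raw decoding errors
#'
#' Fits the DoG curve to continuous signed errors (e.g. IEM decoding errors)
#' as a function of `delta` by minimizing the residual sum of squares, from
#' multiple starts. A negative amplitude indicates repulsion from the
#' previous stimulus, positive attraction.
#'
#' @param errors Signed errors in degrees.
#' @param delta Orientation differences in degrees, same length.
#' @return A `dog_fit` object with `amplitude`, `width`, `fwhm`, `rss`, `n`,
#'   `method = "ls"`.
#' @export
fit_dog_ls <- function(errors, delta) {
  keep <- !is.na(errors) & !is.na(delta)
  e <- errors[keep]
  d <- delta[keep]
  rss_fun <- function(par) sum((e - dog(d, par[1], par[2]))^2)
  starts <- expand.grid(A = c(-15, -5, 5, 15), w = c(0.02, 0.05))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(as.numeric(starts[i, ]), rss_fun, method = "L-BFGS-B",
                 lower = c(-90, 0.01), upper = c(90, 0.3))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  structure(
    list(amplitude = best$par[1], width = best$par[2], sigma = NA_real_,
         fwhm = dog_fwhm(best$par[1], best$par[2]),
         rss = best$value, n = length(e), method = "ls"),
    class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, ...) {
  obj <- if (x$method == "mle") sprintf("NLL = %.2f", x$nll) else
    sprintf("RSS = %.2f", x$rss)
  cat(sprintf(
    "<dog_fit (%s)> amplitude = %.2f deg, width = %.4f /deg, FWHM = %.1f deg, %s, n = %d\n",
    x$method, x$amplitude, x$width, x$fwhm, obj, x$n))
  invisible(x)
}

#' Sliding-window bias (and precision) as a function of delta
#'
#' Applies an estimator to all trials whose orientation difference falls in a
#' half-open window `[center - window/2, center + window/2)` (circularly, so
#' a window centered at 16 degrees with the default width spans `[0, 32)`),
#' stepping the center along a grid.
#'
#' @param data Trial data frame. For `estimator = "psychometric"` it needs
#'   `delta`, `probe_offset`, `response`; for `"circular"` it needs `delta`
#'   and `error` (continuous decoding errors, degrees).
#' @param window Window width in degrees (default 32).
#' @param step Center step in degrees (default 1).
#' @param estimator `"psychometric"` (binary responses, returns `mu` and
#'   `sigma`) or `"circular"` (returns circular mean and SD of errors).
#' @param min_n Windows with fewer trials are reported as `NA` rather than 0.
#' @inheritParams fit_psychometric
#' @return Tibble with columns `center`, `n`, `bias`, `sigma`.
#' @export
sliding_bias <- function(data, window = 32, step = 1,
                         estimator = c("psychometric", "circular"),
                         min_n = 10, guess_rate = 0.25) {
  estimator <- match.arg(estimator)
  centers <- seq(-90, 90, by = step)
  purrr::map_dfr(centers, function(ctr) {
    off <- wrap_ori(data$delta - ctr)
    sub <- data[off >= -window / 2 & off < window / 2, ]
    if (nrow(sub) < min_n) {
      return(tibble::tibble(center = ctr, n = nrow(sub),
                            bias = NA_real_, sigma = NA_real_))
    }
    if (estimator == "psychometric") {
      f <- tryCatch(fit_psychometric(sub, guess_rate = guess_rate),
                    error = function(e) NULL)
      tibble::tibble(center = ctr, n = nrow(sub),
                     bias = if (is.null(f)) NA_real_ else f$mu,
                     sigma = if (is.null(f)) NA_real_ else f$sigma)
    } else {
      tibble::tibble(center = ctr, n = nrow(sub),
                     bias = circ_mean_deg(sub$error),
                     sigma = circ_sd_deg(sub$error))
    }
  })
}

#' Precision following close versus far previous stimuli
#'
#' Splits trials by whether the previous stimulus was within `threshold`
#' degrees of the current one, folds trials with `delta < 0` so bias points
#' in a common direction (sign-flipping the probe offset and response for
#' binary data, or the error for continuous data), subsamples the larger bin
#' to the smaller bin's size `n_resample` times without replacement, and
#' reports the median precision for the subsampled bin alongside the direct
#' estimate for the smaller bin.
#'
#' @inheritParams sliding_bias
#' @param threshold Close/far split on `|delta|`, degrees, in (0, 90).
#' @param n_resample Number of subsampling repetitions (default 31).
#' @param seed Integer seed for the subsampling.
#' @return Tibble with one row per bin: `bin`, `n`, `sigma`, `resampled`.
#' @export
precision_close_far <- function(data, threshold = 30, n_resample = 31,
                                estimator = c("psychometric", "circular"),
                                seed = 1, guess_rate = 0.25) {
  estimator <- match.arg(estimator)
  if (threshold <= 0 || threshold >= 90) {
    rlang::abort("`threshold` must lie in (0, 90) degrees",
                 class = "serialdep_error_threshold")
  }
  folded <- data
  flip <- !is.na(folded$delta) & folded$delta < 0
  if (estimator == "psychometric") {
    folded$probe_offset[flip] <- -folded$probe_offset[flip]
    cw <- response_to_cw(folded$response)
    folded$response <- ifelse(flip, 1 - cw, cw)
  } else {
    folded$error[flip] <- -folded$error[flip]
  }
  est_sigma <- function(sub) {
    if (estimator == "psychometric") {
      fit_psychometric(sub, guess_rate = guess_rate)$sigma
    } else {
      circ_sd_deg(sub$error)
    }
  }
  close <- folded[abs(folded$delta) < threshold, ]
  far <- folded[abs(folded$delta) >= threshold, ]
  if (nrow(close) == 0 || nrow(far) == 0) {
    rlang::abort("both close and far bins must be non-empty",
                 class = "serialdep_error_empty_bin")
  }
  bins <- list(close = close, far = far)
  small <- names(bins)[which.min(vapply(bins, nrow, integer(1)))]
  big <- setdiff(names(bins), small)
  set.seed(seed)
  res <- vapply(seq_len(n_resample), function(i) {
    idx <- sample.int(nrow(bins[[big]]), nrow(bins[[small]]))
    est_sigma(bins[[big]][idx, ])
  }, numeric(1))
  out <- tibble::tibble(
    bin = c(small, big),
    n = c(nrow(bins[[small]]), nrow(bins[[small]])),
    sigma = c(est_sigma(bins[[small]]), stats::median(res)),
    resampled = c(FALSE, TRUE))
  out[order(match(out$bin, c("close", "far"))), ]
}
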