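#' Double-gamma hemodynamic response function
#'
#' Difference of two gamma densities, the standard 6-parameter HRF shape:
#' a positive lobe peaking near `peak_delay` seconds, minus `ratio` times an
#' undershoot lobe peaking near `under_delay` seconds, scaled by `amplitude`.
#' Each lobe is `dgamma(t, shape = delay/disp, scale = disp)`.
#'
#' @param t Time in seconds (vector).
#' @param peak_delay,peak_disp Delay (s) and dispersion of the positive lobe.
#' @param under_delay,under_disp Delay (s) and dispersion of the undershoot.
#' @param ratio Undershoot amplitude relative to the peak (default 1/6).
#' @param amplitude Overall scale.
#' @return Kernel values at `t`.
#' @examples
#' plot(seq(0, 24, 0.8), hrf_double_gamma(seq(0, 24, 0.8)), type = "l")
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, peak_disp = 1,
                             under_delay = 16, under_disp = 1,
                             ratio = 1 / 6, amplitude = 1) {
  stopifnot(peak_delay > 0, peak_disp > 0, under_delay > 0, under_disp > 0)
  amplitude * (stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
                 ratio * stats::dgamma(t, shape = under_delay / under_disp,
                                       scale = under_disp))
}

#' Build an FIR deconvolution design matrix
#'
#' One indicator column per poststimulus lag (`n_taps` columns each for the
#' stimulus and the probe, the k-th column being the onset vector shifted
#' forward by k-1 TRs) plus one constant column per block, giving
#' `2 * n_taps + n_blocks` columns in total.
#'
#' @param onsets_stim,onsets_probe Onset TR indices (1-based, on the TR grid).
#' @param n_tr Total number of TRs.
#' @param blocks Integer/factor vector of length `n_tr` assigning each TR to
#'   a block (run); one constant column is added per level.
#' @param n_taps Number of poststimulus lags modeled (default 30).
#' @return A `fir_design` list with the matrix `X` and column index sets
#'   `stim_cols`, `probe_cols`, `const_cols`.
#' @export
fir_design <- function(onsets_stim, onsets_probe, n_tr, blocks, n_taps = 30) {
  stopifnot(length(blocks) == n_tr)
  check_onsets <- function(on, lab) {
    if (anyDuplicated(on)) {
      rlang::abort(paste0("duplicate ", lab, " onsets"),
                   class = "serialdep_error_onsets")
    }
    if (any(on < 1 | on > n_tr)) {
      rlang::abort(paste0(lab, " onset outside the series"),
                   class = "serialdep_error_onsets")
    }
  }
  check_onsets(onsets_stim, "stimulus")
  check_onsets(onsets_probe, "probe")
  taps <- function(on) {
    m <- matrix(0, n_tr, n_taps)
    for (k in seq_len(n_taps)) {
      rows <- on + k - 1
      rows <- rows[rows <= n_tr]
      m[rows, k] <- 1
    }
    m
  }
  bl <- factor(blocks)
  consts <- vapply(levels(bl), function(l) as.numeric(bl == l),
                   numeric(n_tr))
  X <- cbind(taps(onsets_stim), taps(onsets_probe), consts)
  structure(list(X = X, n_taps = n_taps,
                 stim_cols = seq_len(n_taps),
                 probe_cols = n_taps + seq_len(n_taps),
                 const_cols = 2 * n_taps + seq_len(nlevels(bl))),
            class = "fir_design")
}

#' Estimate voxel HRF kernels by least-squares deconvolution
#'
#' Solves the normal equations `h = (X'X)^-1 X'Y` for an FIR design,
#' separating the stimulus- and probe-evoked kernels. The estimate is
#' independent of stimulus orientation (the design carries onsets only).
#' If `X'X` is singular the minimum-norm least-squares solution is used and
#' a warning is issued.
#'
#' @param Y Numeric matrix, TR x voxel.
#' @param design A [fir_design()].
#' @return List with `stim` and `probe` (tap x voxel kernel matrices) and
#'   `constants` (block x voxel).
#' @export
deconvolve_hrf <- function(Y, design) {
  Y <- as.matrix(Y)
  X <- design$X
  stopifnot(nrow(Y) == nrow(X))
  h <- tryCatch(
    qr.coef(qr(X), Y),
    error = function(e) NULL)
  if (is.null(h) || anyNA(h)) {
    rlang::warn("singular FIR design; using pseudo-inverse least squares")
    h <- MASS::ginv(X) %*% Y
  }
  list(stim = h[design$stim_cols, , drop = FALSE],
       probe = h[design$probe_cols, , drop = FALSE],
       constants = h[design$const_cols, , drop = FALSE])
}

#' Parameterize an FIR kernel with a double-gamma function
#'
#' Least-squares fit of the 6 double-gamma parameters to a deconvolved tap
#' series, from several starting points. Voxels whose fit does not converge
#' (optimizer failure or poor fit, R-squared below `r2_min`) are flagged for
#' exclusion rather than silently kept.
#'
#' @param kernel Tap series (numeric vector, one value per TR lag).
#' @param tr TR in seconds (default 0.8).
#' @param r2_min Minimum variance explained to count as converged.
#' @return A `double_gamma_fit`: list with `par` (named 6-vector),
#'   `fitted`, `r2`, `converged`.
#' @export
fit_hrf_gamma <- function(kernel, tr = 0.8, r2_min = 0.5) {
  if (length(kernel) < 6) {
    rlang::abort("kernel must have at least 6 taps",
                 class = "serialdep_error_kernel")
  }
  t <- (seq_along(kernel) - 1) * tr
  obj <- function(p) {
    if (any(p[1:4] <= 0) || p[5] < 0) return(1e12)
    sum((kernel - hrf_double_gamma(t, p[1], p[2], p[3], p[4], p[5], p[6]))^2)
  }
  amp0 <- max(abs(kernel)) / max(hrf_double_gamma(t))
  starts <- list(c(6, 1, 16, 1, 1 / 6, amp0),
                 c(5, 0.9, 14, 1.2, 0.3, amp0),
                 c(7, 1.2, 18, 0.9, 0.1, -amp0))
  fits <- lapply(starts, function(s) {
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p <- best$par
  fitted <- hrf_double_gamma(t, p[1], p[2], p[3], p[4], p[5], p[6])
  ss_tot <- sum((kernel - mean(kernel))^2)
  r2 <- if (ss_tot > 0) 1 - best$value / ss_tot else 0
  names(p) <- c("peak_delay", "peak_disp", "under_delay", "under_disp",
                "ratio", "amplitude")
  structure(list(par = p, fitted = fitted, r2 = r2,
                 converged = best$convergence == 0 && r2 >= r2_min),
            class = "double_gamma_fit")
}

#' @keywords internal
#' @noRd
place_kernel <- function(n_tr, onset, kernel) {
  out <- numeric(n_tr)
  idx <- onset + seq_along(kernel) - 1
  keep <- idx <= n_tr
  out[idx[keep]] <- kernel[keep]
  out
}

#' Trial-wise response amplitudes from a voxel-specific kernel
#'
#' Builds a design with one regressor per trial per event type (a delta at
#' the onset convolved with the voxel's HRF kernel) plus block constants,
#' and solves for all trial amplitudes simultaneously by least squares.
#' Because every trial's (and the probe's) evoked response is modeled, the
#' estimates remove linear contributions of previous stimulus and probe
#' presentations to the current trial.
#'
#' @param y Voxel time series (length `n_tr`), or a TR x voxel matrix to
#'   solve several voxels that share the same kernel in one pass.
#' @param onsets_stim,onsets_probe Onset TR indices, one per trial.
#' @param kernel Voxel HRF as a tap series, or a `double_gamma_fit` (its
#'   fitted tap series is used).
#' @param blocks Block label per TR.
#' @return For a single series, a tibble with columns `trial`, `beta_stim`,
#'   `beta_probe`; for a matrix, a list with `beta_stim` and `beta_probe`
#'   (trial x voxel matrices).
#' @export
trial_betas <- function(y, onsets_stim, onsets_probe, kernel, blocks) {
  if (inherits(kernel, "double_gamma_fit")) kernel <- kernel$fitted
  multi <- is.matrix(y)
  Y <- if (multi) y else matrix(y, ncol = 1)
  n_tr <- nrow(Y)
  stopifnot(length(onsets_stim) == length(onsets_probe),
            length(blocks) == n_tr)
  n_trials <- length(onsets_stim)
  Xs <- vapply(onsets_stim, place_kernel, numeric(n_tr), n_tr = n_tr,
               kernel = kernel)
  Xp <- vapply(onsets_probe, place_kernel, numeric(n_tr), n_tr = n_tr,
               kernel = kernel)
  bl <- factor(blocks)
  consts <- vapply(levels(bl), function(l) as.numeric(bl == l),
                   numeric(n_tr))
  X <- cbind(Xs, Xp, consts)
  beta <- tryCatch(qr.coef(qr(X), Y), error = function(e) NULL)
  if (is.null(beta) || anyNA(beta)) {
    rlang::warn("rank-deficient trial design; using pseudo-inverse least squares")
    beta <- MASS::ginv(X) %*% Y
  }
  if (multi) {
    list(beta_stim = beta[seq_len(n_trials), , drop = FALSE],
         beta_probe = beta[n_trials + seq_len(n_trials), , drop = FALSE])
  } else {
    tibble::tibble(trial = seq_len(n_trials),
                   beta_stim = unname(beta[seq_len(n_trials), 1]),
                   beta_probe = unname(beta[n_trials + seq_len(n_trials), 1]))
  }
}
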