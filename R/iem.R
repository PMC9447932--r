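#' Orientation channel basis functions
#'
#' Idealized channel tuning: half-wave rectified cosine raised to the 5th
#' power in the doubled-angle convention, `max(0, cos(theta - omega))^5`,
#' evaluated for each of the channel centers. Each channel peaks at 1 on its
#' center and is 0 for orientations 45 degrees or more away (90 degrees away
#' in the doubled space).
#'
#' @param theta Stimulus orientations in degrees.
#' @param centers Channel centers in degrees (default 8 centers evenly
#'   tiling `[0, 180)`).
#' @return Matrix, `length(theta)` x `length(centers)`.
#' @export
iem_basis <- function(theta, centers = iem_centers()) {
  outer(theta, centers, function(th, om) pmax(0, cos(deg2rad2(th - om)))^5)
}

#' Evenly spaced channel centers
#' @param n Number of channels (default 8).
#' @return Centers in degrees.
#' @export
iem_centers <- function(n = 8) seq(0, 180, length.out = n + 1)[-(n + 1)]

#' Train an inverted encoding model
#'
#' Estimates the channel-to-voxel weight matrix `W = pinv(C) B`, where `C`
#' is the channel design built from the training orientations and `B` the
#' trial x voxel activity. Deterministic; the pseudo-inverse is computed by
#' SVD.
#'
#' @param B Training activity, trial x voxel.
#' @param theta Training orientations, degrees.
#' @param centers Channel centers.
#' @return An `iem_fit` with `weights` (channel x voxel) and `centers`.
#' @export
iem_train <- function(B, theta, centers = iem_centers()) {
  B <- as.matrix(B)
  stopifnot(nrow(B) == length(theta))
  C <- iem_basis(theta, centers)
  if (nrow(C) < ncol(C) || qr(C)$rank < ncol(C)) {
    rlang::abort(paste0(
      "rank-deficient channel design: ", nrow(C), " trials at orientations ",
      "spanning too little of the space for ", ncol(C), " channels"),
      class = "serialdep_error_rank")
  }
  structure(list(weights = MASS::ginv(C) %*% B, centers = centers),
            class = "iem_fit")
}

#' Decode orientations from voxel patterns
#'
#' Reconstructs channel responses `Chat = B pinv(W)` and converts each
#' trial's channel profile to an orientation estimate by taking the vector
#' mean over channel centers in the doubled-angle space. The vector angle
#' (halved back) is the decoded orientation and the vector length a proxy
#' for model certainty; trials with a (near-)zero resultant are flagged
#' undefined (`NA` orientation) rather than given an arbitrary angle.
#'
#' @param fit An `iem_fit` from [iem_train()].
#' @param B Test activity, trial x voxel.
#' @return Tibble with `theta_hat` (degrees in `[0, 180)`), `certainty`.
#' @export
iem_decode <- function(fit, B) {
  B <- as.matrix(B)
  stopifnot(ncol(B) == ncol(fit$weights))
  Chat <- B %*% MASS::ginv(fit$weights)
  z <- drop(Chat %*% exp(1i * deg2rad2(fit$centers)))
  th <- (Arg(z) * 90 / pi) %% 180
  th[abs(th - 180) < 1e-9] <- 0
  tibble::tibble(
    theta_hat = ifelse(Mod(z) < 1e-12, NA_real_, th),
    certainty = Mod(z))
}

#' Assign consecutive trials to cross-validation folds
#'
#' Leave-one-fold-out folds over sets of consecutive trials (the scanner
#' analysis used folds of 4 blocks of 17 trials = 68 consecutive trials).
#' A trailing partial fold is kept and flagged with a warning.
#'
#' @param n Number of trials.
#' @param fold_size Trials per fold (default 68).
#' @return Integer fold label per trial.
#' @export
cv_folds <- function(n, fold_size = 68) {
  stopifnot(n >= fold_size)
  f <- (seq_len(n) - 1) %/% fold_size + 1
  if (n %% fold_size != 0) {
    rlang::warn(sprintf("trailing partial fold of %d trials", n %% fold_size))
  }
  f
}

#' Leave-one-fold-out IEM decoding
#'
#' Decodes every trial exactly once with a model trained on all other folds.
#' A training fold whose orientations do not span the space raises an error
#' from [iem_train()]; unbalanced (but full-rank) training sets proceed.
#'
#' @param B Activity, trial x voxel.
#' @param theta Presented orientations, degrees.
#' @param folds Fold labels (e.g. from [cv_folds()]); default one fold per
#'   68 consecutive trials.
#' @param centers Channel centers.
#' @return Tibble with `trial`, `fold`, `theta`, `theta_hat`, `certainty`,
#'   `error` (wrapped decoded minus presented, degrees).
#' @export
iem_crossval <- function(B, theta, folds = NULL, centers = iem_centers()) {
  B <- as.matrix(B)
  n <- nrow(B)
  if (is.null(folds)) folds <- cv_folds(n)
  stopifnot(length(folds) == n, length(theta) == n)
  out <- purrr::map_dfr(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- iem_train(B[tr, , drop = FALSE], theta[tr], centers)
    dec <- iem_decode(fit, B[!tr, , drop = FALSE])
    tibble::tibble(trial = which(!tr), fold = f, theta = theta[!tr],
                   theta_hat = dec$theta_hat, certainty = dec$certainty)
  })
  out <- out[order(out$trial), ]
  out$error <- wrap_ori(out$theta_hat - out$theta)
  out
}

#' Two-stage voxel selection from a localizer
#'
#' Stage 1 keeps the half of voxels most selective for the stimulus's
#' spatial location (largest two-sample t statistic for target vs control
#' condition). Stage 2 keeps, of those, the half with the largest one-way
#' ANOVA F statistic across 10-degree orientation bins, retaining about a
#' quarter of the original pool. Deterministic given the data.
#'
#' @param resp Localizer responses, observation x voxel.
#' @param spatial Two-level factor/character per observation (the level
#'   given in `target` is the stimulus location condition).
#' @param orientation Presented orientation per observation, degrees; `NA`
#'   allowed for observations without a grating (excluded from stage 2).
#' @param target Level of `spatial` corresponding to the stimulus location.
#' @param bin_width Orientation bin width for the ANOVA (default 10).
#' @return Sorted integer indices of the retained voxels.
#' @export
select_voxels <- function(resp, spatial, orientation, target = NULL,
                          bin_width = 10) {
  resp <- as.matrix(resp)
  if (ncol(resp) < 4) {
    rlang::abort("need at least 4 voxels", class = "serialdep_error_voxels")
  }
  spatial <- factor(spatial)
  stopifnot(nlevels(spatial) == 2, nrow(resp) == length(spatial))
  if (is.null(target)) target <- levels(spatial)[1]
  tstat <- apply(resp, 2, function(v) {
    stats::t.test(v[spatial == target], v[spatial != target])$statistic
  })
  stage1 <- order(tstat, decreasing = TRUE)[seq_len(ceiling(ncol(resp) / 2))]
  ok <- spatial == target & !is.na(orientation)
  bins <- factor(floor((orientation[ok] %% 180) / bin_width))
  fstat <- apply(resp[ok, stage1, drop = FALSE], 2, function(v) {
    summary(stats::aov(v ~ bins))[[1]][["F value"]][1]
  })
  keep <- stage1[order(fstat, decreasing = TRUE)[seq_len(ceiling(length(stage1) / 2))]]
  sort(keep)
}

#' Dimensionality of activity following close versus far stimuli
#'
#' Splits trials by the distance to the previous stimulus, equates trial
#' counts by subsampling the larger group without replacement, mean-centers
#' each group and eigendecomposes its voxel covariance. Reports the minimum
#' number of components reaching 90% of the variance and the mean (AUC) of
#' the cumulative-variance curve (higher AUC = lower dimensionality).
#'
#' @param B Activity, trial x voxel.
#' @param delta Orientation difference to the previous stimulus, degrees.
#' @param close_thresh Trials with `|delta| <` this are "close" (default 30).
#' @param far_thresh Trials with `|delta| >` this are "far" (default 60).
#' @param var_target Variance fraction for the component count (default 0.9).
#' @param seed Integer seed for the subsampling.
#' @return Tibble with one row per group: `bin`, `n`, `n_components`, `auc`.
#' @export
pca_dim <- function(B, delta, close_thresh = 30, far_thresh = 60,
                    var_target = 0.9, seed = 1) {
  if (far_thresh <= close_thresh) {
    rlang::abort("`far_thresh` must exceed `close_thresh`",
                 class = "serialdep_error_threshold")
  }
  B <- as.matrix(B)
  idx <- list(close = which(abs(delta) < close_thresh),
              far = which(abs(delta) > far_thresh))
  if (any(lengths(idx) == 0)) {
    rlang::abort("both close and far subsets must be non-empty",
                 class = "serialdep_error_empty_bin")
  }
  set.seed(seed)
  m <- min(lengths(idx))
  idx <- lapply(idx, function(i) if (length(i) > m) sample(i, m) else i)
  purrr::map_dfr(names(idx), function(nm) {
    X <- scale(B[idx[[nm]], , drop = FALSE], scale = FALSE)
    ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    cum <- cumsum(ev) / sum(ev)
    tibble::tibble(bin = nm, n = m,
                   n_components = which(cum >= var_target)[1],
                   auc = mean(cum))
  })
}
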