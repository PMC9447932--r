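#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma"), estimate = c(x$mu, x$sigma))
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(nll = x$nll, n = x$n, n_dropped = x$n_dropped,
                 guess_rate = x$guess_rate, boundary = x$boundary)
}

#' @export
tidy.dog_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "width", "sigma"),
                 estimate = c(x$amplitude, x$width, x$sigma))
}

#' @export
glance.dog_fit <- function(x, ...) {
  tibble::tibble(fwhm = x$fwhm, objective = if (x$method == "mle") x$nll else x$rss,
                 method = x$method, n = x$n)
}

#' @export
tidy.encoding_fit <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x)[, c("fold", "gamma_m", "gamma_s")],
                      -"fold", names_to = "term", values_to = "estimate")
}

#' @export
glance.encoding_fit <- function(x, ...) {
  tibble::tibble(gamma_m = mean(x$gamma_m), gamma_s = mean(x$gamma_s),
                 rss = sum(x$rss), n_folds = nrow(x))
}

#' @export
tidy.readout_fit <- function(x, ...) {
  pn <- attr(x, "par_names")
  tidyr::pivot_longer(tibble::as_tibble(x)[, c("fold", pn)],
                      -"fold", names_to = "term", values_to = "estimate")
}

#' @export
glance.readout_fit <- function(x, ...) {
  pn <- attr(x, "par_names")
  out <- tibble::tibble(decoder = attr(x, "decoder"),
                        p1 = mean(x[[pn[1]]]), p2 = mean(x[[pn[2]]]),
                        sigma = attr(x, "sigma"),
                        loglik_test = -sum(x$nll_test), n_folds = nrow(x))
  names(out)[2:3] <- pn
  out
}
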