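#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decoder bias curve
#'
#' @param object A `bias_curve` from [model_bias_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bias_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta, y = .data$bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = expression(Delta * theta ~ "(deg)"),
                  y = "decoded bias (deg)",
                  title = paste(attr(object, "decoder"), "readout")) +
    ggplot2::theme_minimal()
}

#' Plot a decoded likelihood profile
#'
#' Shows the normalized posterior over orientation with the decoded (MAP)
#' orientation marked.
#'
#' @param object A `likelihood_profile` from [decode_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.likelihood_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta, y = .data$posterior)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "map"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "orientation (deg)", y = "posterior probability",
                  title = paste(attr(object, "decoder"), "decoder")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted DoG bias curve
#'
#' @param object A `dog_fit`.
#' @param delta_max Half-range of the abscissa, degrees.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dog_fit <- function(object, delta_max = 90, ...) {
  d <- seq(-delta_max, delta_max, length.out = 361)
  df <- tibble::tibble(delta = d, bias = dog(d, object$amplitude, object$width))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8, colour = "steelblue") +
    ggplot2::labs(x = expression(Delta * theta ~ "(deg)"), y = "bias (deg)",
                  title = sprintf("DoG fit: A = %.2f deg, FWHM = %.1f deg",
                                  object$amplitude, object$fwhm)) +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window bias curve
#'
#' @param sliding Output of [sliding_bias()].
#' @return A ggplot with bias and precision panels.
#' @export
plot_sliding_bias <- function(sliding) {
  long <- tidyr::pivot_longer(sliding, c("bias", "sigma"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$center, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = expression(Delta * theta ~ "window center (deg)"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
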