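# ggplot2 views of the result types.  Each autoplot() returns a plain
# ggplot object the user can restyle.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_segment geom_hline geom_abline labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a fitted RBSARMAX or Gaussian ARMAX model
#'
#' Observed series with the one-step fitted conditional means overlaid.
#'
#' @param object a fit from [rbsarmax_fit()] or [gaussian_armax_fit()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rbsarmax <- function(object, ...) {
  d <- object$fitted
  ggplot(d, aes(x = .data$t)) +
    geom_line(aes(y = .data$y), colour = "grey40") +
    geom_line(aes(y = .data$mu), colour = "#2166ac", na.rm = TRUE) +
    labs(x = "t", y = object$response,
         title = sprintf("%s fit: observed (grey) and one-step fitted mean (blue)",
                         if (inherits(object, "gaussian_armax")) "Gaussian ARMAX" else "RBSARMAX")) +
    theme_minimal()
}

#' Plot a simulated residual envelope
#'
#' QQ plot of the ordered residuals against the reference-law quantiles,
#' with the simulated envelope band and median.
#'
#' @param object an envelope from [envelope()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rbsarmax_envelope <- function(object, ...) {
  type <- attr(object, "type")
  ggplot(object, aes(x = .data$theoretical)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "grey80", alpha = 0.8) +
    geom_line(aes(y = .data$median), linetype = 2, colour = "grey40") +
    geom_point(aes(y = .data$observed), size = 0.8) +
    labs(x = if (type == "cox-snell") "EXP(1) quantiles" else "N(0,1) quantiles",
         y = "ordered residuals",
         title = sprintf("%s residuals with %d%% simulated envelope",
                         if (type == "cox-snell") "Generalized Cox-Snell" else "Randomized quantile",
                         round(100 * attr(object, "level")))) +
    theme_minimal()
}

#' Stem plot of sample autocorrelations
#'
#' @param object a tibble from [tidy_acf()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rbsarmax_acf <- function(object, ...) {
  partial <- isTRUE(attr(object, "partial"))
  b <- object$bound[1L]
  ggplot(object, aes(x = .data$lag, y = .data$value)) +
    geom_hline(yintercept = 0) +
    geom_hline(yintercept = c(-b, b), linetype = 2, colour = "#2166ac") +
    geom_segment(aes(xend = .data$lag, yend = 0)) +
    geom_point(size = 0.9) +
    labs(x = "lag", y = if (partial) "PACF" else "ACF") +
    theme_minimal()
}
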