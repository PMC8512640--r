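#' The reparameterized Birnbaum-Saunders (RBS) distribution
#'
#' Density, distribution function, quantile function, random generation and
#' moments for the Birnbaum-Saunders distribution parameterized by its mean
#' `mu` and a precision/shape parameter `delta`.  The classical
#' BS(\eqn{\alpha}, \eqn{\lambda}) law maps to this parameterization through
#' \eqn{\mu = \lambda(1 + \alpha^2/2)} and \eqn{\delta = 2/\alpha^2}, so
#' RBS(\eqn{\mu}, \eqn{\delta}) is BS with shape \eqn{\sqrt{2/\delta}} and
#' scale \eqn{\delta\mu/(\delta+1)}.
#'
#' The distribution lives on the positive half-line, is unimodal and
#' right-skewed, has mean \eqn{\mu}, variance
#' \eqn{\mu^2 (2\delta+5)/(\delta+1)^2} and median \eqn{\delta\mu/(\delta+1)}.
#' For fixed \eqn{\mu} the variance vanishes as \eqn{\delta \to \infty} and
#' tends to \eqn{5\mu^2} as \eqn{\delta \to 0}, which is what makes
#' \eqn{\delta} a precision parameter.  The mean parameterization is what
#' allows GLM-style regression on the original data scale.
#'
#' All functions are vectorized over their numeric arguments in the usual
#' recycling fashion.  Invalid inputs (`y <= 0`, probabilities outside (0,1),
#' non-positive parameters) raise errors rather than returning `NaN`: the
#' model-fitting code guards the conditional mean explicitly, so a domain
#' violation here always indicates a programming error worth surfacing.
#'
#' @param x,y vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param mu mean parameter, positive.
#' @param delta precision/shape parameter, positive.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(Y \le y)}, otherwise \eqn{P(Y > y)}.
#'
#' @return `drbs` gives the density, `prbs` the distribution function, `qrbs`
#'   the quantile function and `rrbs` random deviates of length `n`.
#'   `rbs_moments` returns a tibble with columns `mean`, `variance`, `cv` and
#'   `median`.
#'
#' @examples
#' drbs(1, mu = 1, delta = 8)
#' prbs(qrbs(0.9, mu = 2, delta = 15), mu = 2, delta = 15)
#' rbs_moments(mu = 1, delta = 8)
#' @name rbs
NULL

check_rbs_params <- function(mu, delta) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    abort("`mu` must be finite and strictly positive.")
  }
  if (any(!is.finite(delta)) || any(delta <= 0)) {
    abort("`delta` must be finite and strictly positive.")
  }
  invisible(NULL)
}

# Standard-normal argument of the BS transform: z such that F(y) = Phi(z).
rbs_z <- function(y, mu, delta) {
  s <- (delta + 1) * y / (mu * delta)
  sqrt(delta / 2) * (sqrt(s) - 1 / sqrt(s))
}

#' @rdname rbs
#' @export
drbs <- function(x, mu, delta, log = FALSE) {
  check_rbs_params(mu, delta)
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("`x` must be finite and strictly positive (RBS support is (0, Inf)).")
  }
  lam <- mu * delta / (delta + 1)
  alpha <- sqrt(2 / delta)
  # log f = log phi(z(y)) + log z'(y); stable for large delta since z stays
  # moderate near the bulk and dnorm(log = TRUE) never overflows.
  lz <- dnorm(rbs_z(x, mu, delta), log = TRUE)
  ljac <- log(x + lam) - log(2 * alpha) - 0.5 * log(lam) - 1.5 * log(x)
  out <- lz + ljac
  if (log) out else exp(out)
}

#' @rdname rbs
#' @export
prbs <- function(y, mu, delta, lower.tail = TRUE, log.p = FALSE) {
  check_rbs_params(mu, delta)
  if (any(!is.finite(y)) || any(y <= 0)) {
    abort("`y` must be finite and strictly positive (RBS support is (0, Inf)).")
  }
  pnorm(rbs_z(y, mu, delta), lower.tail = lower.tail, log.p = log.p)
}

#' @rdname rbs
#' @export
qrbs <- function(p, mu, delta) {
  check_rbs_params(mu, delta)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1).")
  }
  z <- qnorm(p)
  (mu * delta / (delta + 1)) * (z / sqrt(2 * delta) +
    sqrt(z^2 / (2 * delta) + 1))^2
}

#' @rdname rbs
#' @export
rrbs <- function(n, mu, delta) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    abort("`n` must be a single count >= 1.")
  }
  check_rbs_params(mu, delta)
  z <- rnorm(n)
  (mu * delta / (delta + 1)) * (z / sqrt(2 * delta) +
    sqrt(z^2 / (2 * delta) + 1))^2
}

#' @rdname rbs
#' @export
rbs_moments <- function(mu, delta) {
  check_rbs_params(mu, delta)
  cv <- sqrt(2 * delta + 5) / (delta + 1)
  tibble::tibble(
    mean = mu + 0 * delta,
    variance = mu^2 * cv^2,
    cv = cv + 0 * mu,
    median = delta * mu / (delta + 1)
  )
}

#' Convert between the classical and mean-based Birnbaum-Saunders
#' parameterizations
#'
#' The classical fatigue-life parameterization BS(\eqn{\alpha}, \eqn{\lambda})
#' uses a shape \eqn{\alpha} and a scale \eqn{\lambda} (also the median); the
#' mean-based parameterization RBS(\eqn{\mu}, \eqn{\delta}) uses the mean and
#' a precision.  The maps are exact: \eqn{\mu = \lambda(1+\alpha^2/2)},
#' \eqn{\delta = 2/\alpha^2}, inverted by \eqn{\alpha = \sqrt{2/\delta}},
#' \eqn{\lambda = \delta\mu/(\delta+1)}.
#'
#' @param alpha,lambda classical shape and scale, positive.
#' @param mu,delta mean and precision, positive.
#' @return A tibble with the converted parameter pair, one row per input.
#' @examples
#' bs_to_rbs(alpha = 1, lambda = 1) # mu = 1.5, delta = 2
#' rbs_to_bs(bs_to_rbs(0.5, 2)$mu, bs_to_rbs(0.5, 2)$delta)
#' @export
bs_to_rbs <- function(alpha, lambda) {
  if (any(alpha <= 0) || any(lambda <= 0)) {
    abort("`alpha` and `lambda` must be strictly positive.")
  }
  tibble::tibble(mu = lambda * (1 + alpha^2 / 2), delta = 2 / alpha^2)
}

#' @rdname bs_to_rbs
#' @export
rbs_to_bs <- function(mu, delta) {
  check_rbs_params(mu, delta)
  tibble::tibble(alpha = sqrt(2 / delta), lambda = delta * mu / (delta + 1))
}
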