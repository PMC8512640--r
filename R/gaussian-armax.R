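#' Fit a Gaussian ARMAX baseline by conditional least squares
#'
#' Fits the same conditional-mean recursion as [rbsarmax_fit()] (identity
#' link) but with Gaussian innovations: \eqn{y_t \mid F_{t-1} \sim
#' N(\mu_t, \sigma^2)}.  Estimation minimizes the conditional sum of squares
#' over \eqn{(\eta, \beta, \phi, \theta)} on exactly the same index set
#' \eqn{t = m+1, \dots, n} as the RBSARMAX fit, and \eqn{\sigma^2} is the
#' mean squared conditional residual, so log-likelihoods, AIC/BIC and MAPE
#' of the two models are directly comparable.
#'
#' @inheritParams rbsarmax_fit
#' @return An object of class `"gaussian_armax"` with the same components
#'   and methods as an `"rbsarmax"` fit; `coefficients` holds `sigma2` in
#'   place of `delta`.
#' @examples
#' sim <- rbsarmax_sim(200, delta = 8, eta = 1, beta = 0.7,
#'                     phi = 0.5, theta = 0.3, seed = 1)
#' gfit <- gaussian_armax_fit(sim, order = c(1, 1), xreg = "x1")
#' glance(gfit)
#' @export
gaussian_armax_fit <- function(data, order = c(1, 0), response = "y",
                               xreg = NULL, init = NULL,
                               control = rbsarmax_control()) {
  sd <- as_series_data(data, response, xreg)
  p <- as.integer(order[1])
  q <- as.integer(order[2])
  if (p < 0 || q < 0) abort("`order` components must be non-negative.")
  r <- sd$r
  m <- max(p, q)
  k <- p + q + r + 2L
  n <- sd$n
  n_used <- n - m
  if (n <= m + k) {
    abort(sprintf("Need n > m + k = %d observations; got %d.", m + k, n))
  }
  idx <- (m + 1L):n
  yt <- sd$y[idx]

  start <- if (is.null(init)) default_init(sd$y, sd$X, p, q)[-1L] else as.numeric(init)
  if (length(start) != k - 1L) {
    abort(sprintf("`init` must have length %d (eta, beta, phi, theta).", k - 1L))
  }
  opt <- css_optim(sd$y, sd$X, p, q, r, start, control)
  sigma2 <- opt$value / n_used
  est <- c(sigma2, opt$par)
  nm <- c("sigma2", par_names(p, q, r, sd$xreg))
  names(est) <- nm
  loglik <- -0.5 * n_used * (log(2 * pi * sigma2) + 1)

  negll <- function(par) {
    s2 <- par[1L]
    if (!is.finite(s2) || s2 <= 0) return(1e10)
    0.5 * sum(log(2 * pi * s2) + (yt - mu_of(par[-1L]))^2 / s2)
  }
  mu_of <- function(par) {
    th <- split_par(par, p, q, r)
    armax_recursion(sd$y, sd$X, th$eta, th$beta, th$phi, th$theta)$alpha[idx]
  }

  vc <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  se <- setNames(rep(NA_real_, k), nm)
  if (isTRUE(control$hessian)) {
    H <- tryCatch(optimHess(est, negll), error = function(e) NULL)
    if (!is.null(H)) {
      vci <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vci) && all(is.finite(diag(vci))) && all(diag(vci) > 0)) {
        vc[] <- vci
        se <- setNames(sqrt(diag(vci)), nm)
      }
    }
  }

  th <- split_par(opt$par, p, q, r)
  rec <- armax_recursion(sd$y, sd$X, th$eta, th$beta, th$phi, th$theta)

  structure(list(
    coefficients = est,
    se = se,
    vcov = vc,
    loglik = loglik,
    order = list(p = p, q = q, r = r),
    m = m,
    k = k,
    link = "identity",
    n = n,
    n_used = n_used,
    converged = opt$convergence == 0L,
    n_iter = unname(opt$counts[1L]),
    init = c(sigma2 = NA_real_, setNames(start, nm[-1L])),
    fitted = tibble::tibble(t = seq_len(n), y = sd$y,
                            alpha = rec$alpha, mu = rec$alpha),
    err = rec$err,
    y = sd$y,
    X = sd$X,
    response = sd$response,
    xreg = sd$xreg,
    call = match.call()
  ), class = c("gaussian_armax", "rbsarmax"))
}

# Conditional sum-of-squares minimization of the shared mean recursion.
css_optim <- function(y, X, p, q, r, start, control) {
  n <- length(y)
  m <- max(p, q)
  idx <- (m + 1L):n
  yt <- y[idx]
  css <- function(par) {
    th <- split_par(par, p, q, r)
    rec <- armax_recursion(y, X, th$eta, th$beta, th$phi, th$theta)
    mu <- rec$alpha[idx]
    if (any(!is.finite(mu))) return(1e10)
    sum((yt - mu)^2)
  }
  optim(start, css,
    method = "BFGS",
    control = list(maxit = control$maxit, reltol = control$reltol)
  )
}
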