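#' @export
print.rbsarmax <- function(x, digits = 4, ...) {
  o <- x$order
  dist <- if (inherits(x, "gaussian_armax")) "Gaussian ARMAX" else "RBSARMAX"
  cat(sprintf("%s(%d, %d, %d) fit by conditional %s\n", dist, o$p, o$q, o$r,
              if (inherits(x, "gaussian_armax")) "least squares" else "maximum likelihood"))
  cat(sprintf("n = %d (conditioning on the first %d observations; n used = %d)\n",
              x$n, x$m, x$n_used))
  cat("\nCoefficients:\n")
  cm <- cbind(estimate = x$coefficients, std.error = x$se)
  print(round(cm, digits))
  cat(sprintf("\nlog-likelihood = %.*f   AIC = %.*f   BIC = %.*f\n",
              digits, x$loglik, digits, AIC(x), digits, BIC(x)))
  if (!x$converged) cat("Warning: optimizer did not report convergence.\n")
  invisible(x)
}

#' @export
coef.rbsarmax <- function(object, ...) object$coefficients

#' @export
vcov.rbsarmax <- function(object, ...) object$vcov

#' @export
logLik.rbsarmax <- function(object, ...) {
  structure(object$loglik,
    df = object$k, nobs = object$n_used,
    class = "logLik"
  )
}

#' @export
nobs.rbsarmax <- function(object, ...) object$n_used

#' @export
fitted.rbsarmax <- function(object, ...) object$fitted$mu

#' Conditional survival probabilities of the observed series
#'
#' Internal generic: \eqn{\hat S(y_t \mid F_{t-1})} for \eqn{t = m+1..n},
#' under the fitted conditional law.  This is the single quantity both
#' residual types are built from.
#' @keywords internal
#' @noRd
cond_surv <- function(object) UseMethod("cond_surv")

#' @export
cond_surv.rbsarmax <- function(object) {
  idx <- (object$m + 1L):object$n
  prbs(object$y[idx], object$fitted$mu[idx], object$coefficients[["delta"]],
       lower.tail = FALSE)
}

#' @export
cond_surv.gaussian_armax <- function(object) {
  idx <- (object$m + 1L):object$n
  pnorm(object$y[idx],
        mean = object$fitted$mu[idx],
        sd = sqrt(object$coefficients[["sigma2"]]),
        lower.tail = FALSE)
}

#' Residuals for RBSARMAX and Gaussian ARMAX fits
#'
#' Two distributional residuals are available, both driven by the estimated
#' conditional survival \eqn{\hat S(y_t \mid F_{t-1})}:
#' * `"cox-snell"` - generalized Cox-Snell,
#'   \eqn{r_t = -\log \hat S(y_t \mid F_{t-1})}; unit exponential under a
#'   correctly specified model.
#' * `"quantile"` - randomized quantile residual,
#'   \eqn{r_t = \Phi^{-1}[\hat S(y_t \mid F_{t-1})]} (the survival
#'   convention; set `convention = "cdf"` for the equivalent
#'   \eqn{\Phi^{-1}[\hat F]}, which only flips the sign); standard normal
#'   under correct specification.
#' * `"response"` - raw \eqn{y_t - \hat\mu_t}.
#'
#' Residuals are defined for \eqn{t = m+1, \dots, n}; the conditioned-on
#' head is dropped.  Survival values that underflow to 0 or 1 are clipped to
#' the smallest representable probability with a warning, so the Cox-Snell
#' transform stays finite.
#'
#' @param object a fit from [rbsarmax_fit()] or [gaussian_armax_fit()].
#' @param type residual type, see above.
#' @param convention sign convention for quantile residuals.
#' @param ... unused.
#' @return A numeric vector of length `n - m`.
#' @export
residuals.rbsarmax <- function(object,
                               type = c("quantile", "cox-snell", "response"),
                               convention = c("survival", "cdf"), ...) {
  type <- match.arg(type)
  convention <- match.arg(convention)
  idx <- (object$m + 1L):object$n
  if (type == "response") {
    return(object$y[idx] - object$fitted$mu[idx])
  }
  s <- cond_surv(object)
  tiny <- .Machine$double.xmin
  if (any(s < tiny) || any(s > 1 - 1e-16)) {
    warn("Conditional survival probabilities under/overflowed; clipping.")
    s <- pmin(pmax(s, tiny), 1 - 1e-16)
  }
  switch(type,
    "cox-snell" = -log(s),
    "quantile" = if (convention == "survival") qnorm(s) else qnorm(1 - s)
  )
}

#' Forecast from a fitted RBSARMAX or Gaussian ARMAX model
#'
#' In-sample one-step predictions are the fitted conditional means
#' \eqn{\hat\mu_t}.  Multi-step forecasts iterate the conditional-mean
#' recursion beyond the sample, substituting forecasts for unobserved
#' responses and 0 for future MA innovations.  For an identity-link AR
#' model with \eqn{|\hat\phi_1| < 1} and no regressors the forecast path
#' converges to \eqn{\hat\eta / (1 - \sum_i \hat\phi_i)}.
#'
#' @param object a fitted model.
#' @param h forecast horizon (ignored with a warning when `new_data` sets it).
#' @param new_data optional data frame with `h` rows carrying the future
#'   regressor values (required when the model has regressors).
#' @param ... unused.
#' @return A tibble with columns `t` (continuing the sample index), `h` and
#'   `mu` (forecast conditional mean).
#' @export
predict.rbsarmax <- function(object, h = 1L, new_data = NULL, ...) {
  r <- object$order$r
  if (r > 0L) {
    if (is.null(new_data)) {
      abort("The model has regressors; supply `new_data` with their future values.")
    }
    missing_x <- setdiff(object$xreg, names(new_data))
    if (length(missing_x) > 0) {
      abort(sprintf("`new_data` is missing regressor column(s): %s.",
                    paste(missing_x, collapse = ", ")))
    }
    Xf <- as.matrix(as.data.frame(new_data)[, object$xreg, drop = FALSE])
    h <- nrow(Xf)
    xbf <- drop(Xf %*% object$coefficients[paste0("beta_", object$xreg)])
  } else {
    Xf <- NULL
    xbf <- numeric(h)
  }
  if (h < 1L) abort("`h` must be at least 1.")

  cf <- object$coefficients
  p <- object$order$p
  q <- object$order$q
  eta <- cf[["eta"]]
  phi <- if (p > 0) unname(cf[paste0("phi", seq_len(p))]) else numeric()
  theta <- if (q > 0) unname(cf[paste0("theta", seq_len(q))]) else numeric()
  lk <- link_fun(object$link)

  n <- object$n
  gy_ext <- c(lk$g(object$y), rep(NA_real_, h)) # g-scale "history", extended
  xb_ext <- c(if (is.null(object$X)) numeric(n) else {
    drop(object$X %*% cf[paste0("beta_", object$xreg)])
  }, xbf)
  err_ext <- c(object$err, rep(0, h)) # future innovations are 0

  mu_fc <- numeric(h)
  for (step in seq_len(h)) {
    t <- n + step
    a <- eta + xb_ext[t]
    if (p > 0) a <- a + sum(phi * (gy_ext[t - seq_len(p)] - xb_ext[t - seq_len(p)]))
    if (q > 0) a <- a + sum(theta * err_ext[t - seq_len(q)])
    mu <- lk$ginv(a)
    if (!is.finite(mu) || mu <= 0) {
      abort(sprintf("Forecast conditional mean is non-positive at step %d (mu = %.4g).",
                    step, mu))
    }
    mu_fc[step] <- mu
    gy_ext[t] <- a # forecasts stand in for unobserved g(y)
  }
  tibble::tibble(t = n + seq_len(h), h = seq_len(h), mu = mu_fc)
}

#' @rdname rbsarmax_fit
#' @param x,object a fitted `"rbsarmax"` or `"gaussian_armax"` object.
#' @param ... unused.
#' @export
tidy.rbsarmax <- function(x, ...) {
  est <- x$coefficients
  se <- x$se
  stat <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * pnorm(abs(stat), lower.tail = FALSE))
  )
}

#' @rdname rbsarmax_fit
#' @export
glance.rbsarmax <- function(x, ...) {
  idx <- (x$m + 1L):x$n
  tibble::tibble(
    logLik = x$loglik,
    AIC = AIC(x),
    BIC = BIC(x),
    MAPE = mape(x$y[idx], x$fitted$mu[idx]),
    RMSE = rmse(x$y[idx], x$fitted$mu[idx]),
    nobs = x$n_used,
    df = x$k,
    converged = x$converged,
    n_iter = x$n_iter
  )
}

#' @rdname rbsarmax_fit
#' @export
augment.rbsarmax <- function(x, ...) {
  out <- x$fitted
  res_q <- rep(NA_real_, x$n)
  res_g <- rep(NA_real_, x$n)
  idx <- (x$m + 1L):x$n
  res_q[idx] <- residuals(x, type = "quantile")
  res_g[idx] <- residuals(x, type = "cox-snell")
  out$.resid <- out$y - out$mu
  out$.resid_quantile <- res_q
  out$.resid_coxsnell <- res_g
  out
}
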