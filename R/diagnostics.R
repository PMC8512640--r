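# Residual diagnostics: simulated envelopes for QQ assessment and tidy
# ACF/PACF for order identification.

# Simulate a new response series from a fitted model, conditional on the
# observed covariates and the observed first m values.
simulate_from_fit <- function(object) {
  cf <- object$coefficients
  p <- object$order$p
  q <- object$order$q
  m <- object$m
  phi <- if (p > 0) unname(cf[paste0("phi", seq_len(p))]) else numeric()
  theta <- if (q > 0) unname(cf[paste0("theta", seq_len(q))]) else numeric()
  beta <- if (object$order$r > 0) unname(cf[paste0("beta_", object$xreg)]) else numeric()
  rdist <- if (inherits(object, "gaussian_armax")) {
    s <- sqrt(cf[["sigma2"]])
    function(mu) rnorm(length(mu), mu, s)
  } else {
    d <- cf[["delta"]]
    function(mu) rrbs(length(mu), mu, d)
  }
  sim <- sim_engine(object$n, cf[["eta"]], beta, phi, theta, object$X,
                    burn_in = 0L, link = object$link, rdist = rdist,
                    y_init = if (m > 0) object$y[seq_len(m)] else NULL)
  sim$y
}

refit_like <- function(object, y_new) {
  dat <- tibble::as_tibble(as.data.frame(
    c(setNames(list(y_new), object$response),
      if (object$order$r > 0) as.data.frame(object$X))
  ))
  ctrl <- rbsarmax_control(hessian = FALSE)
  if (inherits(object, "gaussian_armax")) {
    gaussian_armax_fit(dat, order = c(object$order$p, object$order$q),
                       response = object$response, xreg = object$xreg,
                       init = unname(object$coefficients[-1L]), control = ctrl)
  } else {
    rbsarmax_fit(dat, order = c(object$order$p, object$order$q),
                 response = object$response, xreg = object$xreg,
                 link = object$link,
                 init = unname(object$coefficients), control = ctrl)
  }
}

#' Simulated envelope for residual QQ assessment
#'
#' Builds a Monte Carlo envelope around the ordered residuals of a fitted
#' model: `n_sim` response series are simulated from the fitted model
#' (conditional on the observed regressors), each is refitted (warm-started
#' at the original estimates), and per order statistic the envelope is the
#' lower/upper `level` quantile across replicates, together with the
#' replicate median.  Observed ordered residuals falling largely inside the
#' band support the distributional specification.
#'
#' @param object a fit from [rbsarmax_fit()] or [gaussian_armax_fit()].
#' @param type residual type: `"quantile"` (reference N(0,1)) or
#'   `"cox-snell"` (reference EXP(1)).
#' @param n_sim number of simulated replicates (default 100).
#' @param level envelope coverage level (default 0.95).
#' @param seed optional integer seed.
#' @return A tibble of class `"rbsarmax_envelope"` with one row per order
#'   statistic: `theoretical` (reference-law quantile at the plotting
#'   position), `observed`, `lower`, `median`, `upper`, plus attributes
#'   `type`, `level` and `n_failed` (replicates whose refit failed; more
#'   than 20% failing is an error).  Plot with [ggplot2::autoplot()].
#' @export
envelope <- function(object, type = c("quantile", "cox-snell"),
                     n_sim = 100L, level = 0.95, seed = NULL) {
  type <- match.arg(type)
  if (n_sim < 1) abort("`n_sim` must be at least 1.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  obs <- sort(residuals(object, type = type))
  nr <- length(obs)
  with_seed(seed, {
    sims <- vector("list", n_sim)
    done <- 0L
    n_failed <- 0L
    attempts <- 0L
    while (done < n_sim && attempts < 10L * n_sim) {
      attempts <- attempts + 1L
      # identity-link paths with a non-positive conditional mean are not
      # realizations of the fitted model: redraw them, like the MC harness
      y_new <- tryCatch(simulate_from_fit(object), error = function(e) NULL)
      if (is.null(y_new)) next
      res_i <- tryCatch(
        sort(residuals(refit_like(object, y_new), type = type)),
        error = function(e) NULL
      )
      if (is.null(res_i)) {
        n_failed <- n_failed + 1L
        if (n_failed > 0.2 * n_sim) {
          abort(sprintf("Envelope refits failed for %d of %d replicates.",
                        n_failed, n_sim))
        }
        next
      }
      done <- done + 1L
      sims[[done]] <- res_i
    }
    if (done < n_sim) {
      abort(sprintf("Could only complete %d of %d envelope replicates.", done, n_sim))
    }
    mat <- do.call(rbind, sims[seq_len(done)])
    lo <- (1 - level) / 2
    pp <- (seq_len(nr) - 0.5) / nr
    out <- tibble::tibble(
      theoretical = if (type == "cox-snell") qexp(pp) else qnorm(pp),
      observed = obs,
      lower = apply(mat, 2, quantile, probs = lo),
      median = apply(mat, 2, quantile, probs = 0.5),
      upper = apply(mat, 2, quantile, probs = 1 - lo)
    )
    attr(out, "type") <- type
    attr(out, "level") <- level
    attr(out, "n_failed") <- n_failed
    class(out) <- c("rbsarmax_envelope", class(out))
    out
  })
}

#' Tidy sample autocorrelations
#'
#' Sample ACF (biased n-denominator convention, lag 0 equal to 1) or PACF of
#' a series, with the white-noise 95% bound \eqn{\pm z_{0.975}/\sqrt{n}},
#' as a tibble ready for plotting or programmatic order identification.
#'
#' @param x numeric series (constant series are an error: autocorrelation
#'   is undefined).
#' @param lag_max maximum lag (must be below the series length).
#' @param partial if `TRUE` return partial autocorrelations (lags 1..`lag_max`),
#'   otherwise autocorrelations (lags 0..`lag_max`).
#' @return A tibble of class `"rbsarmax_acf"` with columns `lag`, `value`,
#'   `bound` and `significant`.
#' @examples
#' tidy_acf(as.numeric(arima.sim(list(ar = 0.8), 500)), lag_max = 10)
#' @export
tidy_acf <- function(x, lag_max = 36L, partial = FALSE) {
  x <- as.numeric(x)
  if (length(x) <= lag_max) abort("Series length must exceed `lag_max`.")
  if (sd(x) == 0) abort("Autocorrelation is undefined for a constant series.")
  n <- length(x)
  bound <- qnorm(0.975) / sqrt(n)
  if (partial) {
    v <- drop(pacf(x, lag.max = lag_max, plot = FALSE)$acf)
    lag <- seq_len(lag_max)
  } else {
    v <- drop(acf(x, lag.max = lag_max, plot = FALSE)$acf)
    lag <- 0:lag_max
  }
  out <- tibble::tibble(lag = lag, value = v, bound = bound,
                        significant = abs(v) > bound & lag > 0)
  attr(out, "partial") <- partial
  class(out) <- c("rbsarmax_acf", class(out))
  out
}
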