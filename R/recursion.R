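# Conditional-mean recursion shared by the RBSARMAX and Gaussian ARMAX fits,
# the simulators and the forecaster.
#
# On the link scale the linear predictor is
#   alpha_t = eta + x_t'beta - sum_i phi_i x_{t-i}'beta
#           + sum_i phi_i g(y_{t-i}) + sum_j theta_j [g(y_{t-j}) - alpha_{t-j}]
# for t = m+1, ..., n with m = max(p, q).  The likelihood conditions on the
# first m observations: MA innovations g(y_{t-j}) - alpha_{t-j} are defined
# as 0 whenever t-j <= m, and AR terms use the observed series.

link_fun <- function(link) {
  switch(link,
    identity = list(g = identity, ginv = identity),
    log = list(g = log, ginv = exp),
    abort(sprintf("Unknown link '%s'; use 'identity' or 'log'.", link))
  )
}

# Returns list(alpha, err): alpha is NA for t <= m, err is the innovation
# series g(y_t) - alpha_t (0 for t <= m).
armax_recursion <- function(y, X, eta, beta, phi, theta, link = "identity") {
  n <- length(y)
  p <- length(phi)
  q <- length(theta)
  m <- max(p, q, 0L)
  if (n <= m) abort("Series length must exceed m = max(p, q).")
  lk <- link_fun(link)
  gy <- lk$g(y)
  xb <- if (length(beta) > 0L) drop(X %*% beta) else numeric(n)
  base <- eta + xb
  idx <- (m + 1L):n
  if (p > 0L) {
    for (i in seq_len(p)) {
      base[idx] <- base[idx] + phi[i] * (gy[idx - i] - xb[idx - i])
    }
  }
  alpha <- rep(NA_real_, n)
  err <- numeric(n)
  if (q == 0L) {
    alpha[idx] <- base[idx]
    err[idx] <- gy[idx] - base[idx]
  } else if (q == 1L) {
    # unrolled q = 1 loop: the common case in the simulation studies
    th <- theta[1L]
    e_prev <- err[m] # 0 by construction (t - 1 = m is conditioned on)
    for (t in idx) {
      a <- base[t] + th * e_prev
      alpha[t] <- a
      e_prev <- gy[t] - a
      err[t] <- e_prev
    }
  } else {
    for (t in idx) {
      a <- base[t] + sum(theta * err[t - seq_len(q)])
      alpha[t] <- a
      err[t] <- gy[t] - a
    }
  }
  list(alpha = alpha, err = err, xb = xb, m = m)
}

# Conditional means mu_t for t = m+1..n (NA-headed full-length vector).
armax_mu <- function(rec, link = "identity") {
  link_fun(link)$ginv(rec$alpha)
}

split_par <- function(par, p, q, r) {
  list(
    eta = par[1L],
    beta = if (r > 0L) par[1L + seq_len(r)] else numeric(),
    phi = if (p > 0L) par[1L + r + seq_len(p)] else numeric(),
    theta = if (q > 0L) par[1L + r + p + seq_len(q)] else numeric()
  )
}

par_names <- function(p, q, r, xnames = NULL) {
  bn <- if (r > 0L) {
    if (is.null(xnames)) paste0("beta", seq_len(r)) else paste0("beta_", xnames)
  } else {
    character()
  }
  c(
    "eta", bn,
    if (p > 0L) paste0("phi", seq_len(p)) else character(),
    if (q > 0L) paste0("theta", seq_len(q)) else character()
  )
}
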