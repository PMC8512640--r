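# Independent oracles used across the suite.  These are deliberately written
# from first principles (textbook formulas, quadrature, root finding,
# hand-unrolled recursions) and never call the package's own kernels.

# Classical Birnbaum-Saunders density, straight from the fatigue-life
# textbook form: f(t) = phi(a(t)) * a'(t), a(t) = (sqrt(t/lam) - sqrt(lam/t)) / alpha.
bs_pdf_oracle <- function(t, alpha, lam) {
  a <- (sqrt(t / lam) - sqrt(lam / t)) / alpha
  da <- (1 / (2 * alpha)) * (1 / sqrt(t * lam) + sqrt(lam) / t^1.5)
  dnorm(a) * da
}

# Hand-unrolled linear predictor for p = 1, q = 1, r = 1, identity link:
# alpha_t = eta + x_t b - phi x_{t-1} b + phi y_{t-1} + theta (y_{t-1} - alpha_{t-1}),
# with the innovation defined as 0 when t - 1 <= m (= 1).
unrolled_alpha_111 <- function(y, x, eta, b, phi, theta) {
  n <- length(y)
  alpha <- rep(NA_real_, n)
  for (t in 2:n) {
    innov <- if (t - 1 <= 1) 0 else y[t - 1] - alpha[t - 1]
    alpha[t] <- eta + x[t] * b - phi * x[t - 1] * b + phi * y[t - 1] +
      theta * innov
  }
  alpha
}

# Durbin-Levinson partial autocorrelations from a sample ACF vector
# (rho[1] = lag-1, ...): the classical recursion, no shortcuts.
durbin_levinson_pacf <- function(rho) {
  k_max <- length(rho)
  pacf_out <- numeric(k_max)
  phi_prev <- numeric(0)
  for (k in seq_len(k_max)) {
    if (k == 1) {
      phi_k <- rho[1]
    } else {
      num <- rho[k] - sum(phi_prev * rho[(k - 1):1])
      den <- 1 - sum(phi_prev * rho[1:(k - 1)])
      phi_k <- num / den
    }
    pacf_out[k] <- phi_k
    phi_prev <- if (k == 1) phi_k else c(phi_prev - phi_k * rev(phi_prev), phi_k)
  }
  pacf_out
}

sample_acf_oracle <- function(x, k_max) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  vapply(seq_len(k_max), function(k) {
    sum(xc[1:(n - k)] * xc[(k + 1):n]) / denom
  }, numeric(1))
}

# Deterministic simulation that walks the seed forward past identity-link
# paths on which the conditional mean goes non-positive (which the simulator
# treats as errors).
sim_feasible <- function(seed, ...) {
  for (s in seed + 0:199) {
    out <- tryCatch(rbsarmax_sim(..., seed = s), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("no feasible simulation seed found")
}

# A reproducible small (1,1,1) fixture used by several files.
fixture_sim <- function(n = 300, seed = 42) {
  sim_feasible(seed, n = n, delta = 8, eta = 1, beta = 0.7, phi = 0.7,
               theta = 0.5)
}
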