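test_that("residual transforms satisfy their defining identities", {
  sim <- fixture_sim(n = 200, seed = 71)
  fit <- rbsarmax_fit(sim, order = c(1, 1), xreg = "x1",
                      control = rbsarmax_control(hessian = FALSE))
  idx <- 2:nrow(sim)
  s <- prbs(sim$y[idx], fit$fitted$mu[idx], coef(fit)[["delta"]],
            lower.tail = FALSE)
  gcs <- residuals(fit, type = "cox-snell")
  rq <- residuals(fit, type = "quantile")

  expect_equal(gcs, -log(s), tolerance = 1e-12)
  expect_equal(rq, qnorm(s), tolerance = 1e-12)
  # survival and CDF conventions differ only in sign
  expect_equal(residuals(fit, type = "quantile", convention = "cdf"), -rq,
               tolerance = 1e-12)
  # an observation at the conditional median maps to -log(1/2) and 0
  j <- idx[5]
  y_med <- qrbs(0.5, fit$fitted$mu[j], coef(fit)[["delta"]])
  s_med <- prbs(y_med, fit$fitted$mu[j], coef(fit)[["delta"]],
                lower.tail = FALSE)
  expect_equal(-log(s_med), log(2), tolerance = 1e-12)
  expect_equal(qnorm(s_med), 0, tolerance = 1e-12)
  # GCS and RQ are monotone transforms of one another: same ranks (reversed
  # under the survival convention for RQ)
  expect_identical(order(gcs), order(-rq))
  expect_true(all(gcs >= 0))
})

test_that("residuals follow their reference laws on correctly specified fits", {
  # a handful of replicates at moderate n keeps this cheap; the acceptance
  # suite runs the full 100-replicate version at n = 1000
  pass_gcs <- 0L
  pass_rq <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    sim <- sim_feasible(7100 + 10 * i, n = 500, delta = 8, eta = 1,
                        beta = 0.7, phi = 0.5, theta = 0.3)
    fit <- rbsarmax_fit(sim, order = c(1, 1), xreg = "x1",
                        control = rbsarmax_control(hessian = FALSE))
    gcs <- residuals(fit, type = "cox-snell")
    rq <- residuals(fit, type = "quantile")
    if (suppressWarnings(ks.test(gcs, "pexp"))$p.value > 0.01) pass_gcs <- pass_gcs + 1L
    if (suppressWarnings(ks.test(rq, "pnorm"))$p.value > 0.01) pass_rq <- pass_rq + 1L
  }
  expect_gte(pass_gcs, reps - 2L)
  expect_gte(pass_rq, reps - 2L)
})

test_that("envelope construction is seeded, degenerates correctly and covers", {
  sim <- fixture_sim(n = 150, seed = 73)
  fit <- rbsarmax_fit(sim, order = c(1, 1), xreg = "x1",
                      control = rbsarmax_control(hessian = FALSE))

  e1 <- envelope(fit, type = "quantile", n_sim = 5, seed = 11)
  e2 <- envelope(fit, type = "quantile", n_sim = 5, seed = 11)
  expect_identical(e1, e2)

  # with a single replicate the band collapses onto that replicate
  e0 <- envelope(fit, type = "cox-snell", n_sim = 1, seed = 12)
  expect_equal(e0$lower, e0$upper)
  expect_equal(e0$lower, e0$median)

  # bands widen with the level
  e90 <- envelope(fit, type = "quantile", n_sim = 40, level = 0.90, seed = 13)
  e99 <- envelope(fit, type = "quantile", n_sim = 40, level = 0.99, seed = 13)
  expect_true(all(e99$upper - e99$lower >= e90$upper - e90$lower - 1e-12))

  # observed residuals from the generating model fall inside a 95% band at
  # most positions; order statistics are strongly correlated, so the
  # per-realization coverage is noisy and is averaged over fixtures
  cov <- vapply(c(42, 101, 202), function(sd) {
    simc <- fixture_sim(n = 150, seed = sd)
    fitc <- rbsarmax_fit(simc, order = c(1, 1), xreg = "x1",
                         control = rbsarmax_control(hessian = FALSE))
    ec <- envelope(fitc, type = "quantile", n_sim = 50, seed = 14)
    mean(ec$observed >= ec$lower & ec$observed <= ec$upper)
  }, numeric(1))
  expect_gte(mean(cov), 0.85)
  expect_gte(min(cov), 0.6)
})

test_that("sample ACF and PACF match first-principles oracles", {
  set.seed(75)
  x <- as.numeric(arima.sim(list(ar = 0.8), 600))
  a <- tidy_acf(x, lag_max = 12)
  expect_equal(a$value[1], 1) # lag 0
  expect_equal(a$value[-1], sample_acf_oracle(x, 12), tolerance = 1e-12)

  p <- tidy_acf(x, lag_max = 12, partial = TRUE)
  expect_equal(p$value, durbin_levinson_pacf(sample_acf_oracle(x, 12)),
               tolerance = 1e-10)
  # PACF(1) = ACF(1) exactly
  expect_equal(p$value[1], a$value[2])
  expect_equal(a$bound[1], qnorm(0.975) / sqrt(600))
  expect_error(tidy_acf(rep(1, 50)), "constant")
})

test_that("AR(1) autocorrelation structure is recovered at large n", {
  set.seed(76)
  x <- as.numeric(arima.sim(list(ar = 0.8), 5000))
  a <- tidy_acf(x, lag_max = 10)
  expect_equal(a$value[2], 0.8, tolerance = 0.05)
  p <- tidy_acf(x, lag_max = 10, partial = TRUE)
  # cut-off after lag 1
  expect_gte(mean(abs(p$value[-1]) < p$bound[1]), 0.8)
})
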