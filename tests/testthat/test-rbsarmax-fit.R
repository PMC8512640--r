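test_that("linear predictor recursion matches a hand-unrolled evaluation", {
  y <- c(1.2, 2.0, 1.5, 3.1, 2.4, 1.8)
  x <- c(0.3, 0.8, 0.1, 0.9, 0.5, 0.2)
  alpha <- armax_recursion(y, matrix(x, ncol = 1), eta = 1, beta = 0.7,
                           phi = 0.7, theta = 0.5)$alpha
  expect_equal(alpha, unrolled_alpha_111(y, x, 1, 0.7, 0.7, 0.5))

  # p = q = 0 reduces to the static regression mean
  a0 <- armax_recursion(y, matrix(x, ncol = 1), 1, 0.7,
                        numeric(), numeric())$alpha
  expect_equal(a0, 1 + 0.7 * x)

  # pure AR(1) one-step arithmetic
  a1 <- armax_recursion(c(2, 5), NULL, eta = 1, beta = numeric(),
                        phi = 0.5, theta = numeric())$alpha
  expect_equal(a1[2], 1 + 0.5 * 2)
  expect_error(armax_recursion(c(1, 2), NULL, 1, numeric(), c(0.1, 0.1, 0.1),
                               numeric()), "exceed")
})

test_that("conditional log-likelihood is the sum of conditional RBS log-densities", {
  sim <- fixture_sim(n = 120, seed = 5)
  fit <- rbsarmax_fit(sim, order = c(1, 1), xreg = "x1",
                      control = rbsarmax_control(hessian = FALSE))
  cf <- coef(fit)
  rec <- armax_recursion(sim$y, as.matrix(sim[, "x1"]), cf[["eta"]],
                         cf[["beta_x1"]], cf[["phi1"]], cf[["theta1"]])
  idx <- 2:nrow(sim)
  expect_equal(fit$loglik,
               sum(drbs(sim$y[idx], rec$alpha[idx], cf[["delta"]], log = TRUE)),
               tolerance = 1e-10)
  # logLik carries df and nobs so AIC/BIC follow the -2l + penalty forms
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 5)
  expect_equal(attr(ll, "nobs"), 119)
  expect_equal(AIC(fit), aic(fit$loglik, 5))
  expect_equal(BIC(fit), bic(fit$loglik, 5, 119))
})

test_that("likelihood is scale-equivariant: y -> c y shifts l by -(n - m) log c", {
  sim <- fixture_sim(n = 150, seed = 9)
  cf <- c(delta = 8, eta = 1, beta = 0.7, phi = 0.7, theta = 0.5)
  ll_at <- function(dat, eta, beta) {
    rec <- armax_recursion(dat$y, as.matrix(dat[, "x1"]), eta, beta, 0.7, 0.5)
    idx <- 2:nrow(dat)
    sum(drbs(dat$y[idx], rec$alpha[idx], 8, log = TRUE))
  }
  l1 <- ll_at(sim, 1, 0.7)
  cc <- 3.7
  sim2 <- sim
  sim2$y <- cc * sim$y
  l2 <- ll_at(sim2, cc * 1, cc * 0.7)
  expect_equal(l2, l1 - (nrow(sim) - 1) * log(cc), tolerance = 1e-8)
})

test_that("fit with p = q = 0 agrees with an independent RBS regression fit", {
  set.seed(31)
  n <- 400
  x <- runif(n)
  mu <- 1 + 2 * x
  dat <- tibble::tibble(y = rrbs(n, mu, 10), x1 = x)
  fit <- rbsarmax_fit(dat, order = c(0, 0), xreg = "x1")

  # independent-observation ML fit written directly against the density
  nll <- function(par) {
    -sum(drbs(dat$y, par[2] + par[3] * x, exp(par[1]), log = TRUE))
  }
  direct <- optim(c(log(10), 1, 2), nll, method = "BFGS",
                  control = list(reltol = 1e-12))
  expect_equal(fit$loglik, -direct$value, tolerance = 1e-5)
  expect_equal(unname(coef(fit)[c("eta", "beta_x1")]),
               direct$par[2:3], tolerance = 1e-3)
  # large-ish n recovery: estimates within 3 se of truth
  expect_lt(abs(coef(fit)[["beta_x1"]] - 2), 3 * fit$se[["beta_x1"]])
  expect_lt(abs(coef(fit)[["eta"]] - 1), 3 * fit$se[["eta"]])
})

test_that("refitting from the optimum leaves the log-likelihood fixed", {
  sim <- fixture_sim(n = 200, seed = 13)
  fit <- rbsarmax_fit(sim, order = c(1, 1), xreg = "x1",
                      control = rbsarmax_control(hessian = FALSE))
  refit <- rbsarmax_fit(sim, order = c(1, 1), xreg = "x1",
                        init = unname(coef(fit)),
                        control = rbsarmax_control(hessian = FALSE))
  expect_lt(abs(refit$loglik - fit$loglik), 1e-6)
  expect_true(fit$converged)
})

test_that("default initialization follows the OLS / zero-dynamics / moment rules", {
  set.seed(77)
  x <- runif(100)
  y <- rrbs(100, 2 + x, 20)
  init <- default_init(y, matrix(x, ncol = 1), p = 2, q = 1)
  expect_length(init, 2 + 2 + 1 + 1) # delta, eta, beta, phi x2, theta
  expect_equal(init[4:6], c(0, 0, 0)) # dynamics start at zero
  ols <- coef(lm(y ~ x))
  expect_equal(init[2:3], unname(ols), tolerance = 1e-10)
  expect_gte(init[1], 0.5)
  # constant response with no regressors starts at its own level
  init_c <- default_init(rep(3, 50), NULL, 1, 0)
  expect_equal(init_c[2], 3)
})

test_that("the conditional likelihood depends only on values and order", {
  sim <- fixture_sim(n = 100, seed = 21)
  fit1 <- rbsarmax_fit(sim, order = c(1, 1), xreg = "x1",
                       control = rbsarmax_control(hessian = FALSE))
  relabeled <- sim
  relabeled$t <- sim$t + 1000 # time labels are irrelevant
  fit2 <- rbsarmax_fit(relabeled, order = c(1, 1), xreg = "x1",
                       control = rbsarmax_control(hessian = FALSE))
  expect_identical(fit1$loglik, fit2$loglik)
  expect_identical(coef(fit1), coef(fit2))
})

test_that("true parameters beat a perturbed intercept in likelihood, usually", {
  wins <- 0L
  for (i in 1:30) {
    sim <- sim_feasible(3000 + 10 * i, n = 200, delta = 8, eta = 1,
                        beta = 0.7, phi = 0.5, theta = 0.3)
    ll <- function(eta) {
      rec <- armax_recursion(sim$y, as.matrix(sim[, "x1"]), eta, 0.7, 0.5, 0.3)
      idx <- 2:nrow(sim)
      mu <- rec$alpha[idx]
      if (any(mu <= 0)) return(-Inf)
      sum(drbs(sim$y[idx], mu, 8, log = TRUE))
    }
    if (ll(1) > ll(1.5)) wins <- wins + 1L
  }
  expect_gte(wins, 28)
})

test_that("input validation names the offending row", {
  bad <- tibble::tibble(y = c(1, -2, 3), x1 = c(0.1, 0.2, 0.3))
  expect_error(rbsarmax_fit(bad, order = c(0, 0), xreg = "x1"), "row 2")
  expect_error(rbsarmax_fit(tibble::tibble(y = 1:10 / 10), order = c(0, 0),
                            xreg = "zz"), "not found")
})
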