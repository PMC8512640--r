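test_that("parameterization conversions are exact and mutually inverse", {
  cv <- bs_to_rbs(alpha = 1, lambda = 1)
  expect_equal(cv$mu, 1.5)
  expect_equal(cv$delta, 2)

  cv2 <- bs_to_rbs(alpha = sqrt(2 / 50), lambda = 50 / 51)
  expect_equal(cv2$mu, 1)
  expect_equal(cv2$delta, 50)

  # round trip is the identity to machine precision on a parameter grid
  for (a in c(0.1, 0.5, 1, 2)) {
    for (l in c(0.2, 1, 10)) {
      back <- rbs_to_bs(bs_to_rbs(a, l)$mu, bs_to_rbs(a, l)$delta)
      expect_equal(back$alpha, a, tolerance = 1e-12)
      expect_equal(back$lambda, l, tolerance = 1e-12)
    }
  }
  expect_error(bs_to_rbs(-1, 1), "positive")
  expect_error(rbs_to_bs(1, 0), "delta")
})

test_that("density matches the classical BS density under conversion and integrates to 1", {
  # pointwise agreement with an independently coded BS density
  grid <- seq(0.05, 10, length.out = 100)
  expect_equal(
    drbs(grid, mu = 2, delta = 15),
    bs_pdf_oracle(grid, alpha = sqrt(2 / 15), lam = 15 * 2 / 16),
    tolerance = 1e-12
  )
  # quadrature oracle: unit mass across the delta x mu grid
  for (d in c(0.5, 2, 8, 50)) {
    for (m in c(0.5, 1, 10)) {
      mass <- integrate(function(y) drbs(y, m, d), 0, Inf, rel.tol = 1e-9)$value
      expect_equal(mass, 1, tolerance = 1e-7)
    }
  }
  # tails vanish
  expect_lt(drbs(1e-8, 1, 8), 1e-12)
  expect_lt(drbs(1e4, 1, 8), 1e-12)
  # log form stays finite at the very large precision seen in applications
  expect_true(is.finite(drbs(88, mu = 88, delta = 1e4, log = TRUE)))
  expect_error(drbs(-1, 1, 8), "positive")
})

test_that("CDF, survival and quantile functions are consistent", {
  # the median is delta*mu/(delta+1) for any parameter pair
  for (m in c(0.5, 3)) {
    for (d in c(2, 25)) {
      med <- d * m / (d + 1)
      expect_equal(prbs(med, m, d), 0.5, tolerance = 1e-12)
      expect_equal(prbs(med, m, d, lower.tail = FALSE), 0.5, tolerance = 1e-12)
      expect_equal(qrbs(0.5, m, d), med, tolerance = 1e-12)
    }
  }
  # CDF agrees with quadrature of the density
  for (y0 in c(0.5, 1, 2)) {
    cdf_quad <- integrate(function(y) drbs(y, 1, 8), 0, y0, rel.tol = 1e-10)$value
    expect_equal(prbs(y0, 1, 8), cdf_quad, tolerance = 1e-8)
    expect_equal(prbs(y0, 1, 8, lower.tail = FALSE), 1 - cdf_quad, tolerance = 1e-8)
  }
  # CDF and quantile are mutual inverses
  q <- seq(0.01, 0.99, by = 0.01)
  expect_equal(prbs(qrbs(q, 3, 25), 3, 25), q, tolerance = 1e-10)
  # ... and the quantile matches a root-finding oracle on the CDF
  root <- uniroot(function(y) prbs(y, 1, 8) - 0.975, c(1e-6, 100), tol = 1e-12)$root
  expect_equal(qrbs(0.975, 1, 8), root, tolerance = 1e-8)
  # monotone in y, probabilities in (0, 1)
  ps <- prbs(seq(0.1, 5, length.out = 50), 1, 8)
  expect_true(all(diff(ps) > 0) && all(ps > 0) && all(ps < 1))
  expect_error(qrbs(1.2, 1, 8), "inside")
  expect_error(prbs(0, 1, 8), "positive")
})

test_that("moments match their closed forms, limits and quadrature", {
  mo <- rbs_moments(1, 8)
  expect_equal(mo$mean, 1)
  expect_equal(mo$variance, 21 / 81)
  expect_equal(mo$median, 8 / 9)
  # quadrature oracle for the second moment
  m2 <- integrate(function(y) y^2 * drbs(y, 1, 8), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(mo$variance, m2 - 1, tolerance = 1e-7)
  # precision limits: Var -> 0 as delta -> Inf, Var -> 5 mu^2 as delta -> 0
  expect_lt(rbs_moments(1, 1e8)$variance, 1e-6)
  expect_equal(rbs_moments(2, 1e-8)$variance, 20, tolerance = 1e-6)
  # cv in (0, sqrt(5)), decreasing in delta
  cvs <- rbs_moments(1, c(0.01, 0.1, 1, 10, 100))$cv
  expect_true(all(cvs > 0) && all(cvs < sqrt(5)))
  expect_true(all(diff(cvs) < 0))
})

test_that("sampler is seeded, matches its moments and its CDF", {
  s1 <- with(list(), {set.seed(7); rrbs(100, 1, 8)})
  s2 <- with(list(), {set.seed(7); rrbs(100, 1, 8)})
  expect_identical(s1, s2)

  set.seed(991)
  x <- rrbs(50000, 1, 8)
  expect_true(all(x > 0))
  v <- rbs_moments(1, 8)$variance
  expect_lt(abs(mean(x) - 1), 4 * sqrt(v / 50000))

  set.seed(992)
  y <- rrbs(10000, 2, 15)
  ks <- suppressWarnings(ks.test(y, function(q) prbs(q, 2, 15)))
  expect_gt(ks$p.value, 0.01)
  expect_error(rrbs(0, 1, 8), "count")
})
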