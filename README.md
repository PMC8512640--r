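# rbsarmax

Dynamic regression for **positive, right-skewed time series**: an ARMA model
with exogenous regressors whose conditional distribution is the
mean-parameterized (reparameterized) Birnbaum–Saunders law — the
**RBSARMAX(p, q, r)** model.

Weekly mortality counts, pollutant concentrations, rainfall, hospital loads:
such series are strictly positive, skewed to the right, and serially
dependent. Gaussian ARMA modeling either violates the distributional shape
or forces a log transform that changes the scale on which effects are
interpreted. The RBSARMAX model keeps the data on their original scale by
letting the response, conditional on its past, follow the Birnbaum–Saunders
distribution parameterized by its **mean** μ and a **precision** δ
(written RBS(μ, δ); the classical BS(α, λ) law with α = √(2/δ),
λ = δμ/(δ + 1)), while the conditional mean carries a GARMA-style linear
recursion:

```
y_t | F_{t-1} ~ RBS(μ_t, δ)

g(μ_t) = α_t = η + x_t'β − Σᵢ φᵢ x_{t−i}'β + Σᵢ φᵢ g(y_{t−i})
             + Σⱼ θⱼ [ g(y_{t−j}) − α_{t−j} ]
```

with identity link g by default, p autoregressive terms φ, q moving-average
terms θ and r regressors β. Estimation is by **conditional maximum
likelihood** (conditioning on the first m = max(p, q) observations, BFGS,
δ optimized on the log scale), with standard errors from a numerical
Hessian. The package is written tidyverse-style: data frames in, tibbles
out, `tidy()`/`glance()`/`augment()` on fits, `autoplot()` everywhere.

## What's inside

* **Distribution kernel** — `drbs()`, `prbs()`, `qrbs()`, `rrbs()`,
  `rbs_moments()`, `bs_to_rbs()`/`rbs_to_bs()`.
* **Model fitting** — `rbsarmax_fit()` (conditional ML) and
  `gaussian_armax_fit()` (conditional least squares on the same mean
  recursion, the natural baseline), with `predict()` for multi-step
  forecasts.
* **Diagnostics** — generalized Cox–Snell and randomized quantile residuals
  (`residuals()`), simulated QQ envelopes (`envelope()`), tidy ACF/PACF
  (`tidy_acf()`).
* **Simulators** — `rbsarmax_sim()` and the Weibull-innovation
  misspecification generator `weibull_armax_sim()`, plus
  `make_regressors()`.
* **Monte Carlo harness** — `run_mc_cell()`, `mc_summary()`, `run_table()`
  regenerate the estimator bias/MSE and model-comparison study tables.
* **Application workflow** — `read_series_csv()`,
  `build_mortality_design()`, `identify_order()`, `run_application()` for
  the weekly mortality ~ trend + temperature² + particulates analysis, and
  `sim_mortality_example()` for a synthetic stand-in dataset.
* A thin command-line front end in `inst/cli/rbsarmax.R`
  (`simulate` / `fit` / `mc-table` verbs).

## Worked example

Simulate an RBSARMAX(1, 1, 1) series at (δ = 8, η = 1, β = 0.7, φ = 0.7,
θ = 0.5) and refit it:

```r
library(rbsarmax)

sim <- rbsarmax_sim(500, delta = 8, eta = 1, beta = 0.7,
                    phi = 0.7, theta = 0.5, seed = 2024)
fit <- rbsarmax_fit(sim, order = c(1, 1), xreg = "x1")
fit
#> RBSARMAX(1, 1, 1) fit by conditional maximum likelihood
#> n = 500 (conditioning on the first 1 observations; n used = 499)
#>
#> Coefficients:
#>         estimate std.error
#> delta     8.7669    0.5550
#> eta       1.1175    0.0912
#> beta_x1   0.6625    0.0855
#> phi1      0.5735    0.0547
#> theta1    0.5068    0.0261
#>
#> log-likelihood = -729.3645   AIC = 1468.7289   BIC = 1489.7920
```

Every generating parameter is recovered within roughly two standard errors;
`delta` is the precision of the conditional law (larger ⇒ less conditional
spread around μ_t), `phi1`/`theta1` the ARMA dynamics of the conditional
mean, `beta_x1` the regressor effect on the original data scale.

```r
glance(fit)
#> # A tibble: 1 × 9
#>   logLik   AIC   BIC  MAPE  RMSE  nobs    df converged n_iter
#>    <dbl> <dbl> <dbl> <dbl> <dbl> <int> <int> <lgl>      <int>
#> 1  -729. 1469. 1490.  46.0  1.84   499     5 TRUE          36

predict(fit, new_data = tibble::tibble(x1 = c(0.4, 0.6, 0.5)))
#> # A tibble: 3 × 3
#>       t     h    mu
#>   <int> <int> <dbl>
#> 1   501     1  1.80
#> 2   502     2  2.40
#> 3   503     3  2.60
```

The in-sample MAPE of ~46% reflects the large conditional coefficient of
variation at δ = 8 (cv ≈ 0.51): one-step point prediction is intrinsically
noisy at this precision even under the true model. Diagnostics:

```r
residuals(fit, type = "quantile")          # ~ N(0, 1) if well specified
autoplot(envelope(fit, n_sim = 100, seed = 1))
autoplot(tidy_acf(residuals(fit), partial = TRUE))
```

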