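test_that("weighted deviance and standardized residuals follow the binomial form", {
  out <- deviance_and_residuals(0.011, 0.010, 1e6)
  expect_equal(out$residuals, 0.001 / sqrt(0.01 * 0.99 / 1e6), tolerance = 1e-12)
  expect_equal(out$residuals, 10.05, tolerance = 1e-3)

  same <- deviance_and_residuals(c(0.02, 0.03), c(0.02, 0.03), c(1e5, 1e5))
  expect_equal(same$deviance, 0)
  expect_equal(same$residuals, c(0, 0))

  expect_error(deviance_and_residuals(0.5, 0, 100), "inside")
  expect_error(deviance_and_residuals(0.5, 1, 100), "inside")
})

test_that("a nested trend-only fit reproduces pure-logistic data exactly", {
  spec <- model_spec("model1")
  truth <- param_set(spec, alpha = 0.004, beta = c(-2.2, -0.055))
  s <- exact_series(truth, spec, 1940:2010, 5e5)
  fit <- fit_model(s, spec)
  expect_lt(fit$deviance, 1e-6)
  expect_equal(fit$estimate[["beta2"]], -0.055, tolerance = 1e-5)
  expect_equal(fit$df, nrow(s) - 3)
})

test_that("a one-bell exponential-trend truth is recovered from auto start", {
  spec <- model_spec("model2", 1)
  truth <- param_set(spec, beta = c(-3.1, -0.025, 0, 0),
                     excess = list(c(4, log(30), 0.15)))
  s <- exact_series(truth, spec, 1940:2000, 2e5)
  fit <- suppressMessages(fit_model(s, spec))
  expect_lt(fit$deviance, 1e-6)
  truth_v <- excesstrend:::pack_params(truth, spec)
  est <- fit$estimate[setdiff(names(truth_v), c("beta3", "beta4"))]
  expect_equal(est, truth_v[names(est)], tolerance = 1e-4)
})

test_that("initialisation is deterministic and lands near the true bells", {
  s <- make_reference_fixture("EU5-Model1")
  spec <- reference_spec("EU5-Model1")
  i1 <- initialize_parameters(s, spec)
  i2 <- initialize_parameters(s, spec)
  expect_identical(i1, i2)
  expect_equal(i1$excess$mu, c(3.473, 3.782, 4.088), tolerance = 0.2)
  # trend-only request returns a trend-only parameter set
  i0 <- initialize_parameters(s, model_spec("model1"))
  expect_equal(nrow(i0$excess), 0)
})

test_that("fixing a parameter removes it from the free set and the df count", {
  spec <- model_spec("model1")
  truth <- param_set(spec, alpha = 0.004, beta = c(-2.2, -0.055))
  s <- exact_series(truth, spec, 1950:2000, 1e5)
  fit <- fit_model(s, spec, init = truth, fixed = c(beta2 = -0.055))
  expect_false("beta2" %in% fit$free)
  expect_equal(fit$df, nrow(s) - 2)
  expect_equal(fit$params$beta[["beta2"]], -0.055)
  expect_error(fit_model(s, spec, init = truth, fixed = c(nonsense = 1)),
               "unknown fixed")
})

test_that("overdispersion bookkeeping is deviance over residual df", {
  tb <- two_bell_truth()
  s <- simulate_series(sim_config(1950, 2010, 2e5, tb$params, tb$spec, seed = 8))
  fit <- suppressMessages(suppressWarnings(fit_model(s, tb$spec)))
  expect_equal(fit$overdispersion, fit$deviance / fit$df)
  expect_equal(fit$df, nrow(s) - n_free_params(tb$spec))
  td <- tidy(fit)
  expect_equal(td$statistic, td$estimate / td$std.error)
  expect_equal(glance(fit)$nobs, nrow(s))
})

test_that("OD-scaled standard errors inflate by sqrt(overdispersion)", {
  tb <- two_bell_truth()
  s <- simulate_series(sim_config(1950, 2010, 2e5, tb$params, tb$spec,
                                  dispersion = 2e-5, seed = 4))
  f1 <- suppressMessages(suppressWarnings(fit_model(s, tb$spec)))
  f2 <- suppressWarnings(fit_model(s, tb$spec, init = f1$params,
                                   od_scale_se = TRUE))
  expect_equal(unname(f2$se / f1$se),
               rep(sqrt(f2$overdispersion), length(f1$se)),
               tolerance = 0.02)
})

test_that("Poisson log-linear trend fits recover a generative log-slope", {
  years <- 1934:1990
  t <- years - 1930
  rate <- exp(-2.8 - 0.021 * t)
  s <- mortality_series(years, rep(2e6, length(years)), round(rate * 2e6))
  fit <- fit_loglinear_trend(s, degree = 1)
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "t"], -0.021, tolerance = 1e-4)
  expect_equal(est$estimate[est$term == "(Intercept)"], -2.8, tolerance = 1e-3)

  # near-constant rate gives a near-zero slope
  s0 <- mortality_series(years, rep(1e6, length(years)), rep(2e4, length(years)))
  fit0 <- fit_loglinear_trend(s0, degree = 1)
  expect_lt(abs(tidy(fit0)$estimate[2]), 1e-8)
})

test_that("window exclusion leaves the retained-year fit unchanged", {
  years <- 1934:2018
  t <- years - 1930
  rate <- exp(-2.5 - 0.03 * t + 2e-4 * t^2)
  set.seed(42)
  deaths <- rbinom(length(years), 1e6, rate)
  s <- mortality_series(years, rep(1e6, length(years)), deaths)
  fx <- fit_loglinear_trend(s, degree = 2, exclude_window = c(1950, 2000))
  s_kept <- suppressMessages(exclude_years(s, 1950:2000))
  fk <- fit_loglinear_trend(s_kept, degree = 2)
  expect_equal(coef(fx$model), coef(fk$model), tolerance = 1e-10)
  # predictions cover the excluded window for excess estimation
  expect_true(all(1950:2000 %in% fx$table$year[fx$table$excluded]))
  expect_error(fit_loglinear_trend(s, 3, exclude_window = c(1930, 2017)),
               "retained")
})

test_that("a stillbirth-style run with reporting dummies recovers the bell mode", {
  iv <- data.frame(kind = c("pulse", "step"), year = c(1994, 1995))
  spec <- model_spec("model2", 1, interventions = iv)
  truth <- param_set(spec, beta = c(-4.6, -0.02, 0, 1e-7),
                     excess = list(c(3, log(42.5), 0.1)), iv = c(0.12, 0.3))
  s <- simulate_series(sim_config(1950, 2020, 8e5, truth, spec, seed = 14))
  fit <- suppressMessages(suppressWarnings(fit_model(s, spec)))
  mode_est <- exp(fit$params$excess$mu[1] - fit$params$excess$sigma[1]^2)
  expect_equal(mode_est, exp(log(42.5) - 0.1^2), tolerance = 0.5)
  expect_equal(fit$estimate[["iv2"]], 0.3, tolerance = 0.1)
})
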