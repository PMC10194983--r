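test_that("excess term evaluates the lognormal bell and guards its domain", {
  tt <- 1:100
  expect_equal(excess_term(tt, a = 0, mu = 3, sigma = 0.2), rep(0, 100))
  # Gaussian factor is 1 at the centre of the bell
  expect_equal(excess_term(20, a = 1, mu = log(20), sigma = 0.1), 1 / 20)
  expect_error(excess_term(0.5, 1, 3, 0.1), "t >= 1")
  expect_error(excess_term(10, 1, 3, 0), "sigma")
})

test_that("numeric mode of each bell matches exp(mu - sigma^2)", {
  grid <- seq(1, 100, by = 0.01)
  cases <- list(c(4.582, 3.473, 0.133), c(1, log(20), 0.1), c(10, 4.0, 0.3),
                c(3, 2.5, 0.05))
  for (cs in cases) {
    y <- excess_term(grid, cs[1], cs[2], cs[3])
    expect_equal(grid[which.max(y)], exp(cs[2] - cs[3]^2), tolerance = 0.06)
  }
})

test_that("floored logistic is stable and identical to the printed form", {
  naive <- function(eta, alpha) alpha + (1 - alpha) / (1 + 1 / exp(eta))
  eta <- c(-700, -30, -5, 0, 5, 30, 700)
  expect_equal(excesstrend:::floored_logistic(eta, 0.0048), naive(eta, 0.0048),
               tolerance = 1e-14)
  # no overflow far beyond the naive form's range
  big <- excesstrend:::floored_logistic(c(-5000, 5000), 0.01)
  expect_true(all(is.finite(big)))
  expect_equal(big, c(0.01, 1))
})

test_that("linear predictor assembles trend, bells, ties and dummies", {
  spec0 <- model_spec("model2")
  p0 <- param_set(spec0, beta = c(0, 0, 0, 0))
  expect_equal(linear_predictor(1:10, p0, spec0), rep(0, 10))

  # direct transcription of the exponential-cubic trend at t = 10
  b <- c(-2.729, -0.043, 9.8e-05, 9.0e-07)
  p1 <- param_set(spec0, beta = b)
  expect_equal(linear_predictor(10, p1, spec0),
               b[1] + b[2] * 10 + b[3] * 100 + b[4] * 1000)

  # a tied width always equals its master
  spec_tie <- model_spec("model1", 2, width_ties = c("2" = 1))
  for (sg in c(0.1, 0.37)) {
    p <- param_set(spec_tie, alpha = 0.001, beta = c(-2, -0.05),
                   excess = list(c(1, 3.2, sg), c(2, 3.9, 99)))
    expect_equal(p$excess$sigma[2], sg)
    eta <- linear_predictor(1:50, p, spec_tie)
    manual <- -2 - 0.05 * (1:50) + excess_term(1:50, 1, 3.2, sg) +
      excess_term(1:50, 2, 3.9, sg)
    expect_equal(eta, manual)
  }

  # pulse and step dummies act on calendar years
  spec_iv <- model_spec("model2", interventions = data.frame(
    kind = c("pulse", "step"), year = c(1994, 1995)))
  p_iv <- param_set(spec_iv, beta = c(-3, 0, 0, 0), iv = c(0.5, 0.2))
  t <- (1990:1997) - 1930
  eta <- linear_predictor(t, p_iv, spec_iv)
  expect_equal(eta - (-3), c(0, 0, 0, 0, 0.5, 0.2, 0.2, 0.2))
})

test_that("rates decline monotonically when the trend is pure decline", {
  t <- 1:90
  spec1 <- model_spec("model1")
  p1 <- param_set(spec1, alpha = 0.004, beta = c(-2.7, -0.05))
  expect_true(all(diff(eval_rate(t, p1, spec1)) < 0))
  spec2 <- model_spec("model2")
  p2 <- param_set(spec2, beta = c(-2.7, -0.04, 0, 0))
  expect_true(all(diff(eval_rate(t, p2, spec2)) < 0))
  # and the floored logistic approaches its floor
  expect_equal(eval_rate(5000, p1, spec1), 0.004, tolerance = 1e-10)
})

test_that("undisturbed trend zeroes bells and dummies, not the decline", {
  spec <- reference_spec("EU5-Model1")
  p <- reference_params("EU5-Model1")
  t <- (1950:2000) - 1930
  expect_true(all(eval_rate(t, p, spec) - undisturbed_rate(t, p, spec) >= 0))

  p0 <- p; p0$excess$a[] <- 0
  expect_equal(undisturbed_rate(t, p, spec), eval_rate(t, p0, spec))
  expect_equal(undisturbed_rate(t, p0, spec), eval_rate(t, p0, spec))
})

test_that("well-separated excess curves peak at exp(mu - sigma^2) each", {
  spec <- model_spec("model1", 3)
  p <- param_set(spec, alpha = 0.002, beta = c(-1.5, -0.06),
                 excess = list(c(3, log(25), 0.07), c(8, log(45), 0.07),
                               c(10, log(75), 0.07)))
  grid <- seq(10, 95, by = 0.005)
  diffc <- eval_rate(grid, p, spec) - undisturbed_rate(grid, p, spec)
  for (k in 1:3) {
    mu <- p$excess$mu[k]; sg <- p$excess$sigma[k]
    win <- grid > exp(mu) * 0.8 & grid < exp(mu) * 1.2
    expect_equal(grid[win][which.max(diffc[win])], exp(mu - sg^2),
                 tolerance = 0.1)
  }
})

test_that("eval_rate is continuous in the parameters", {
  spec <- model_spec("model1", 1)
  base <- c(alpha = 0.003, beta1 = -1.6, beta2 = -0.06, a1 = 5, mu1 = 3.5,
            sigma1 = 0.12)
  t <- (1950:2000) - 1930
  r0 <- eval_rate(t, excesstrend:::unpack_params(base, spec), spec)
  for (nm in names(base)) {
    up <- base; up[nm] <- up[nm] + 1e-7 * max(abs(up[nm]), 1)
    r1 <- eval_rate(t, excesstrend:::unpack_params(up, spec), spec)
    expect_lt(max(abs(r1 - r0)), 1e-4)
  }
})

test_that("model structure is validated", {
  expect_error(model_spec("model1", 2, width_ties = c("1" = 2)), "greater")
  expect_error(model_spec("model3", 0), "war-time")
  expect_error(param_set(model_spec("model1"), beta = c(-2, -0.05)), "alpha")
  expect_error(param_set(model_spec("model1"), alpha = 0.001,
                         beta = c(-2, -0.05),
                         excess = list(c(1, 3, 0.1))), "0 excess")
  spec <- model_spec("model2", 1)
  p_bad <- param_set(spec, beta = c(-3, 0, 0, 0), excess = list(c(1, 3, 0.1)))
  expect_error(linear_predictor(1:10, p_bad, model_spec("model1")), "family")
})
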