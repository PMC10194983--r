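test_that("excess bookkeeping is exact arithmetic and vectorises", {
  one <- excess_from_counts(120, 100)
  expect_equal(one$excess, 20)
  expect_equal(one$ratio, 1.2)
  tab <- excess_from_counts(c(100, 200, 50), c(90, 150, 60))
  expect_equal(sum(tab$excess), sum(tab$observed) - sum(tab$expected))
})

test_that("windowed summary uses the undisturbed baseline for E", {
  spec <- reference_spec("EU5-Model1")
  params <- reference_params("EU5-Model1")
  s <- make_reference_fixture("EU5-Model1")
  fit <- fit_model(s, spec, init = params)
  est <- excess_summary(s, fit, window = c(1950, 2000))
  expect_equal(est$observed, sum(s$deaths[s$year <= 2000]))
  base <- undisturbed_rate(s$t[s$year <= 2000], fit$params, spec)
  expect_equal(est$expected, sum(s$births[s$year <= 2000] * base))
  expect_equal(est$observed, est$excess + est$expected)
  expect_gt(est$ratio, 1) # all published amplitudes are positive
  expect_error(excess_summary(s, fit, window = c(1940, 2000)), "missing")
})

test_that("no bells means no excess: O equals E and the ratio is one", {
  spec <- model_spec("model1")
  truth <- param_set(spec, alpha = 0.003, beta = c(-2, -0.05))
  s <- exact_series(truth, spec, 1945:2005, 1e6)
  fit <- fit_model(s, spec, init = truth)
  est <- excess_summary(s, fit, window = c(1950, 2000))
  expect_equal(est$excess, 0, tolerance = 1)
  expect_equal(est$ratio, 1, tolerance = 1e-5)
})

test_that("member-level excesses add up to the pooled total", {
  tb <- two_bell_truth()
  members <- lapply(1:3, function(i) {
    exact_series(tb$params, tb$spec, 1948:2005, 3e5 * i)
  })
  fits <- lapply(members, function(m) fit_model(m, tb$spec, init = tb$params))
  ests <- purrr::map2(members, fits,
                      ~ excess_summary(.x, .y, window = c(1950, 2000)))
  pooled <- suppressMessages(pool_series(members))
  pooled_fit <- fit_model(pooled, tb$spec, init = tb$params)
  pooled_est <- excess_summary(pooled, pooled_fit, window = c(1950, 2000))
  expect_equal(sum(vapply(ests, function(e) e$excess, numeric(1))),
               pooled_est$excess, tolerance = 1e-4 * pooled_est$expected)
})

test_that("slope-fixed refits give an ordered interval around the estimate", {
  tb <- two_bell_truth()
  s <- simulate_series(sim_config(1948, 2010, 5e5, tb$params, tb$spec, seed = 6))
  fit <- suppressMessages(suppressWarnings(fit_model(s, tb$spec)))
  ci <- excess_ci(s, tb$spec, fit, window = c(1950, 2000), level = 0.9)
  expect_lt(ci$excess_lo, ci$excess)
  expect_gt(ci$excess_hi, ci$excess)
  expect_lt(ci$ratio_lo, ci$ratio)
  expect_gt(ci$ratio_hi, ci$ratio)
  expect_lt(ci$param_lo, ci$param_hi)
})

test_that("the lognormal mode converts to a calendar peak year", {
  expect_equal(peak_year(3.473, 0.133), exp(3.473 - 0.133^2) + 1930)
  expect_equal(peak_year(3.473, 0.133), 1961.7, tolerance = 0.05)
  # vanishing width: mode tends to the median
  expect_equal(peak_year(3.5, 1e-9), exp(3.5) + 1930, tolerance = 1e-6)
  # the mode always precedes the median for positive widths
  expect_lt(peak_year(3.8, 0.2), exp(3.8) + 1930)
})

test_that("fitted peak timing carries a delta-method interval, ties included", {
  s <- make_reference_fixture("EU5-Model1")
  spec <- reference_spec("EU5-Model1")
  fit <- fit_model(s, spec, init = reference_params("EU5-Model1"))
  for (k in 1:3) {
    pk <- peak_estimate(fit, k)
    expect_equal(pk$peak_year,
                 peak_year(fit$params$excess$mu[k], fit$params$excess$sigma[k]))
    expect_true(pk$peak_lo < pk$peak_year && pk$peak_year < pk$peak_hi)
  }
  # term 2 shares its width with term 1; the interval must still be finite
  pk2 <- peak_estimate(fit, 2)
  expect_true(is.finite(pk2$peak_lo) && is.finite(pk2$peak_hi))
  expect_error(peak_estimate(fit, 9), "term_index")
})
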