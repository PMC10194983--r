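# Small builders shared across test files. Everything is generated in code;
# no stored data.

toy_series <- function(years = 1950:1952, births = c(1000, 2000, 1500),
                       deaths = c(10, 30, 20)) {
  mortality_series(years, births, deaths)
}

# Noise-free series from an arbitrary parameter set (exact, no rounding).
exact_series <- function(params, spec, years, births) {
  t <- years - spec$time_origin
  rate <- eval_rate(t, params, spec)
  mortality_series(years, rep_len(births, length(years)), rate * births,
                   origin = spec$time_origin)
}

# A well-separated two-bell logistic-decline truth for generative tests.
two_bell_truth <- function() {
  spec <- model_spec("model1", n_excess = 2)
  params <- param_set(spec, alpha = 0.003, beta = c(-1.6, -0.06),
                      excess = list(c(6, log(32), 0.12), c(12, log(55), 0.1)))
  list(spec = spec, params = params)
}

expect_series_equal <- function(a, b) {
  expect_equal(a$year, b$year)
  expect_equal(a$births, b$births)
  expect_equal(a$deaths, b$deaths)
}
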