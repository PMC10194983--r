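#' Lognormal-density excess term
#'
#' The bell-shaped departure added to the linear predictor:
#' `(a / t) * exp(-(log(t) - mu)^2 / (2 * sigma^2))`. As a function of time it
#' is proportional to a lognormal density, so it rises from zero, peaks at
#' `t = exp(mu - sigma^2)` (the lognormal mode) and decays back to zero.
#'
#' @param t Time index (calendar year minus the time origin); must be >= 1 so
#'   that `log(t)` is defined and non-negative.
#' @param a Amplitude.
#' @param mu Location on the log-time axis (`exp(mu)` is the median year
#'   offset).
#' @param sigma Width on the log-time axis; must be positive.
#' @return Numeric vector of contributions, same length as `t`.
#' @export
#' @examples
#' excess_term(20, a = 1, mu = log(20), sigma = 0.1) # 1/20 at the bell centre
excess_term <- function(t, a, mu, sigma) {
  if (any(t < 1)) stop("excess_term requires t >= 1 (log-time must be defined)")
  if (sigma <= 0) stop("sigma must be positive")
  (a / t) * exp(-(log(t) - mu)^2 / (2 * sigma^2))
}

# Intervention dummy contribution on the linear-predictor scale.
intervention_terms <- function(year, spec, iv) {
  out <- numeric(length(year))
  if (!nrow(spec$interventions)) return(out)
  for (j in seq_len(nrow(spec$interventions))) {
    kind <- spec$interventions$kind[j]
    y0 <- spec$interventions$year[j]
    ind <- if (kind == "pulse") as.numeric(year == y0) else as.numeric(year >= y0)
    out <- out + iv[j] * ind
  }
  out
}

#' Linear predictor of a trend-plus-excess model
#'
#' `eta(t) = beta1 + beta2 t (+ beta3 t^2 + beta4 t^3)` plus the sum of
#' lognormal excess terms and intervention dummies. Under `model1` the floor
#' `alpha` is applied outside the linear predictor by [eval_rate()].
#'
#' @inheritParams excess_term
#' @param params A [param_set()].
#' @param spec The matching [model_spec()].
#' @return Numeric vector `eta(t)`.
#' @export
linear_predictor <- function(t, params, spec) {
  stopifnot(inherits(params, "param_set"), inherits(spec, "model_spec"))
  if (params$family != spec$family) {
    stop("param_set family (", params$family, ") does not match spec (", spec$family, ")")
  }
  if (nrow(params$excess) != spec$n_excess) {
    stop("param_set has ", nrow(params$excess), " excess term(s); spec expects ",
         spec$n_excess)
  }
  if (any(t < 1)) stop("linear_predictor requires t >= 1")
  b <- params$beta
  eta <- b[["beta1"]] + b[["beta2"]] * t
  if (spec$family != "model1") {
    eta <- eta + b[["beta3"]] * t^2 + b[["beta4"]] * t^3
  }
  for (k in seq_len(nrow(params$excess))) {
    eta <- eta + excess_term(t, params$excess$a[k], params$excess$mu[k],
                             params$excess$sigma[k])
  }
  eta + intervention_terms(t + spec$time_origin, spec, params$iv)
}

# Numerically stable floored logistic: alpha + (1 - alpha) / (1 + 1/exp(eta)).
floored_logistic <- function(eta, alpha) {
  alpha + (1 - alpha) * stats::plogis(eta)
}

#' Evaluate the model rate at given times
#'
#' `model1`: `alpha + (1 - alpha) * plogis(eta)`, a logistic decline with a
#' lower limit `alpha` (computed in a stable form equivalent to
#' `alpha + (1 - alpha) / (1 + 1/exp(eta))`). `model2`/`model3`: `exp(eta)`.
#' Values outside `(0, 1)` are possible for extreme parameters and are
#' returned as computed, never clamped; validity is the caller's check.
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of rates (proportions).
#' @export
eval_rate <- function(t, params, spec) {
  eta <- linear_predictor(t, params, spec)
  if (anyNA(eta)) stop("NaN/NA in linear predictor; check parameters")
  if (spec$family == "model1") {
    floored_logistic(eta, params$alpha)
  } else {
    exp(eta)
  }
}

#' Undisturbed (secular) trend rate
#'
#' [eval_rate()] with every excess amplitude set to zero, i.e. the smooth
#' decline the model predicts in the absence of the bell-shaped departures.
#' Under `model3` the designated war-time bell is kept in the baseline by
#' default (`zero_ww2 = FALSE`): it describes a disruption that precedes the
#' usual 1950-2000 estimation window, where its mass is negligible, and
#' zeroing it would distort the pre-1950 baseline. Intervention dummies are
#' zeroed by default as well since they model reporting artefacts, not the
#' secular decline; keep them with `zero_interventions = FALSE`.
#'
#' @inheritParams linear_predictor
#' @param zero_interventions Zero the intervention coefficients too? Default
#'   `TRUE`.
#' @param zero_ww2 Also zero the designated war-time term of a `model3` fit?
#'   Default `FALSE`.
#' @return Numeric vector of baseline rates.
#' @export
undisturbed_rate <- function(t, params, spec, zero_interventions = TRUE,
                             zero_ww2 = FALSE) {
  p0 <- params
  keep <- rep(FALSE, nrow(p0$excess))
  if (spec$ww2_term > 0 && !zero_ww2) keep[spec$ww2_term] <- TRUE
  p0$excess$a[!keep] <- 0
  if (zero_interventions) p0$iv[] <- 0
  eval_rate(t, p0, spec)
}
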