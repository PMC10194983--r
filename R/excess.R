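#' Excess-death bookkeeping from observed and expected counts
#'
#' The elementary arithmetic: excess is `observed - expected`, the ratio is
#' `observed / expected`. Vectorised, so a per-country table can be piped
#' through and summed.
#'
#' @param observed Observed death counts.
#' @param expected Expected (model-predicted) death counts.
#' @return A tibble with columns `observed`, `expected`, `excess`, `ratio`.
#' @export
#' @examples
#' excess_from_counts(3329071, 2760447) # excess 568624, ratio 1.206
excess_from_counts <- function(observed, expected) {
  tibble::tibble(observed = observed, expected = expected,
                 excess = observed - expected, ratio = observed / expected)
}

#' Windowed observed / expected excess summary
#'
#' Over an inclusive calendar window, sums the observed deaths (O) and the
#' deaths expected under the fitted model's undisturbed trend (E = births
#' times baseline rate, summed), and reports O, E, O-E and O/E. The baseline
#' comes from the full-data fit with excess amplitudes zeroed (see
#' [undisturbed_rate()]); the window-exclusion alternative lives in
#' [fit_loglinear_trend()].
#'
#' @param series The fitted `mortality_series`.
#' @param fit An `excess_fit` for `series`.
#' @param window `c(first_year, last_year)`, inclusive; every window year
#'   must be present in the series. Default `c(1950, 2000)`.
#' @param zero_ww2,zero_interventions Passed to [undisturbed_rate()].
#' @return A one-row tibble of class `excess_estimate` with columns
#'   `window_start`, `window_end`, `observed`, `expected`, `excess`, `ratio`.
#' @export
excess_summary <- function(series, fit, window = c(1950, 2000),
                           zero_ww2 = FALSE, zero_interventions = TRUE) {
  stopifnot(inherits(fit, "excess_fit"))
  years <- window[1]:window[2]
  missing_years <- setdiff(years, series$year)
  if (length(missing_years)) {
    stop("window year(s) missing from series: ",
         paste(missing_years, collapse = ", "))
  }
  sub <- dplyr::filter(tibble::as_tibble(series), .data$year %in% years)
  t <- sub$year - fit$spec$time_origin
  base <- undisturbed_rate(t, fit$params, fit$spec,
                           zero_interventions = zero_interventions,
                           zero_ww2 = zero_ww2)
  cnt <- excess_from_counts(sum(sub$deaths), sum(sub$births * base))
  out <- tibble::tibble(window_start = window[1], window_end = window[2],
                        observed = cnt$observed, expected = cnt$expected,
                        excess = cnt$excess, ratio = cnt$ratio)
  class(out) <- c("excess_estimate", class(tibble::tibble()))
  out
}

#' Slope-fixed confidence interval for the windowed excess
#'
#' The dominant uncertainty in the expected count E is the secular slope.
#' Following the slope-fixed refit construction, the profile interval for the
#' linear trend coefficient `beta2` is computed first; the model is then
#' refitted with `beta2` fixed at each bound (all other parameters free), E
#' is recomputed from each refit's undisturbed trend, and the implied O-E and
#' O/E at the two bounds form the interval.
#'
#' @inheritParams excess_summary
#' @param spec The [model_spec()] of `fit`.
#' @param level Confidence level, default 0.90.
#' @param param Trend parameter carrying the uncertainty, default `"beta2"`.
#' @return A one-row tibble: point estimates plus `excess_lo`, `excess_hi`,
#'   `ratio_lo`, `ratio_hi`, the `beta2` bounds and the level.
#' @export
excess_ci <- function(series, spec, fit, window = c(1950, 2000), level = 0.90,
                      param = "beta2") {
  point <- excess_summary(series, fit, window)
  ci <- profile_ci(series, spec, fit, param, level = level)
  at_bound <- function(v) {
    refit <- suppressWarnings(fit_model(series, spec, init = fit$params,
                                        fixed = c(stats::setNames(v, param),
                                                  fit$fixed)))
    excess_summary(series, refit, window)
  }
  lo_fit <- at_bound(ci[["lower"]])
  hi_fit <- at_bound(ci[["upper"]])
  tibble::tibble(
    window_start = window[1], window_end = window[2],
    observed = point$observed, expected = point$expected,
    excess = point$excess, ratio = point$ratio,
    excess_lo = min(lo_fit$excess, hi_fit$excess),
    excess_hi = max(lo_fit$excess, hi_fit$excess),
    ratio_lo = min(lo_fit$ratio, hi_fit$ratio),
    ratio_hi = max(lo_fit$ratio, hi_fit$ratio),
    param = param, param_lo = ci[["lower"]], param_hi = ci[["upper"]],
    level = level
  )
}

#' Calendar year of a lognormal excess term's maximum
#'
#' The excess term `(a/t) exp(-(log t - mu)^2 / (2 sigma^2))` peaks at
#' `t = exp(mu - sigma^2)` (the mode of the corresponding lognormal density);
#' the calendar year adds the time origin.
#'
#' @param mu Log-time location.
#' @param sigma Log-time width.
#' @param origin Time origin, default 1930.
#' @return Calendar year of the peak (numeric, fractional years retained).
#' @export
#' @examples
#' peak_year(3.473, 0.133) # about 1961.7
peak_year <- function(mu, sigma, origin = 1930) {
  exp(mu - sigma^2) + origin
}

#' Peak timing of a fitted excess term, with delta-method CI
#'
#' Converts an excess term's `(mu, sigma)` estimates to the calendar year of
#' its maximum via [peak_year()], and propagates their joint uncertainty with
#' the delta method: with `g = exp(mu - sigma^2)`, the gradient is
#' `(g, -2 sigma g)` and the variance follows from the fitted covariance of
#' `(mu, sigma)`. A term whose width is tied uses the master width's estimate
#' and covariance entries.
#'
#' @param fit An `excess_fit`.
#' @param term_index Which excess term (1-based, in time order).
#' @param level CI level, default 0.95.
#' @return A one-row tibble of class `peak_estimate`: `term`, `mu`, `sigma`,
#'   `peak_year`, `peak_lo`, `peak_hi`, `level`.
#' @export
peak_estimate <- function(fit, term_index, level = 0.95) {
  stopifnot(inherits(fit, "excess_fit"))
  spec <- fit$spec
  if (term_index < 1 || term_index > spec$n_excess) {
    stop("term_index must be in 1..", spec$n_excess)
  }
  mu <- fit$params$excess$mu[term_index]
  sigma <- fit$params$excess$sigma[term_index]
  if (sigma <= 0) stop("term width must be positive")
  master <- term_index
  tied <- spec$width_ties
  if (as.character(term_index) %in% names(tied)) {
    master <- tied[[as.character(term_index)]]
  }
  mu_name <- paste0("mu", term_index)
  sig_name <- paste0("sigma", master)
  g <- exp(mu - sigma^2)
  pk <- g + spec$time_origin
  var_pk <- NA_real_
  if (all(c(mu_name, sig_name) %in% rownames(fit$cov))) {
    V <- fit$cov[c(mu_name, sig_name), c(mu_name, sig_name)]
    grad <- c(g, -2 * sigma * g)
    var_pk <- drop(t(grad) %*% V %*% grad)
  }
  z <- stats::qnorm((1 + level) / 2)
  half <- if (is.finite(var_pk)) z * sqrt(max(var_pk, 0)) else NA_real_
  out <- tibble::tibble(term = as.integer(term_index), mu = mu, sigma = sigma,
                        peak_year = pk, peak_lo = pk - half, peak_hi = pk + half,
                        level = level)
  class(out) <- c("peak_estimate", class(tibble::tibble()))
  out
}
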