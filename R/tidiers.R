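#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the free parameters of a trend-plus-excess fit
#'
#' @param x An `excess_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic` (estimate / SE), one row per free parameter.
#' @method tidy excess_fit
#' @export
tidy.excess_fit <- function(x, ...) {
  tibble::tibble(term = x$free, estimate = unname(x$estimate),
                 std.error = unname(x$se), statistic = unname(x$tvalues))
}

#' One-row fit summary
#'
#' @param x An `excess_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `deviance`, `df`, `overdispersion`, `n_free`,
#'   `nobs`, `converged`, `n_iter`.
#' @method glance excess_fit
#' @export
glance.excess_fit <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, df = x$df,
                 overdispersion = x$overdispersion,
                 n_free = length(x$free), nobs = nrow(x$series),
                 converged = x$converged, n_iter = x$n_iter)
}

#' Tidy a Poisson log-linear trend fit
#'
#' @param x A `loglinear_fit`.
#' @param ... Unused.
#' @return Coefficient table as a tibble (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @method tidy loglinear_fit
#' @export
tidy.loglinear_fit <- function(x, ...) {
  cf <- stats::coef(summary(x$model))
  tibble::tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                 std.error = unname(cf[, 2]), statistic = unname(cf[, 3]),
                 p.value = unname(cf[, 4]))
}

#' Augment a fitted series with per-year fit columns
#'
#' @param x An `excess_fit`.
#' @param ... Unused.
#' @return The series tibble plus `fitted` (fitted rate), `undisturbed`
#'   (baseline rate), `excess_rate` (observed minus baseline) and `.resid`
#'   (standardized residual).
#' @method augment excess_fit
#' @export
augment.excess_fit <- function(x, ...) {
  t <- x$series$year - x$spec$time_origin
  base <- undisturbed_rate(t, x$params, x$spec)
  dplyr::mutate(tibble::as_tibble(x$series),
                fitted = x$fitted,
                undisturbed = base,
                excess_rate = .data$rate - base,
                .resid = x$residuals)
}

#' @importFrom generics augment
#' @export
generics::augment

#' Plot a fitted mortality trend
#'
#' `type = "fit"` shows observed rates (per 1000), the fitted curve and the
#' dashed undisturbed trend; `type = "excess"` shows observed-minus-baseline
#' rates with the fitted excess curve; `type = "residuals"` shows
#' standardized residuals with a +/-2 SD band.
#'
#' @param object An `excess_fit`.
#' @param type One of `"fit"`, `"excess"`, `"residuals"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot excess_fit
#' @export
autoplot.excess_fit <- function(object, type = c("fit", "excess", "residuals"),
                                ...) {
  type <- match.arg(type)
  aug <- augment.excess_fit(object)
  if (type == "fit") {
    ggplot2::ggplot(aug, ggplot2::aes(x = .data$year)) +
      ggplot2::geom_point(ggplot2::aes(y = 1000 * .data$rate), size = 0.9) +
      ggplot2::geom_line(ggplot2::aes(y = 1000 * .data$fitted)) +
      ggplot2::geom_line(ggplot2::aes(y = 1000 * .data$undisturbed),
                         linetype = "dashed") +
      ggplot2::labs(x = "year", y = "rate per 1000 live births")
  } else if (type == "excess") {
    ggplot2::ggplot(aug, ggplot2::aes(x = .data$year)) +
      ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
      ggplot2::geom_point(ggplot2::aes(y = 1000 * .data$excess_rate), size = 0.9) +
      ggplot2::geom_line(ggplot2::aes(y = 1000 * (.data$fitted - .data$undisturbed))) +
      ggplot2::labs(x = "year", y = "excess rate per 1000 live births")
  } else {
    ggplot2::ggplot(aug, ggplot2::aes(x = .data$year, y = .data$.resid)) +
      ggplot2::geom_hline(yintercept = c(-2, 0, 2), linetype = c(2, 1, 2),
                          colour = "grey60") +
      ggplot2::geom_point(size = 0.9) +
      ggplot2::labs(x = "year", y = "standardized residual")
  }
}

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data %||%
NULL
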