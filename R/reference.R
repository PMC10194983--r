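# Published reference estimates used as fixture constants. Each entry stores
# the trend family, the excess-term triples (a, mu, sigma) in time order, the
# width-tie structure and the year range the estimates refer to. The UK third
# width is published with a negative sign; sigma enters the model only as
# sigma^2, so the absolute value is stored to satisfy the sigma > 0 invariant.
.reference_table <- list(
  "US-Model1" = list(
    family = "model1", alpha = 0.0048, beta = c(-2.717, -0.050),
    excess = list(c(11.572, 3.534, 0.191), c(14.492, 3.811, 0.191),
                  c(10.202, 4.076, 0.045)),
    ties = c("2" = 1), years = 1934:2018, births = 3.5e6
  ),
  "US-Model2" = list(
    family = "model2", beta = c(-2.729, -0.043, 9.8e-05, 9.0e-07),
    excess = list(c(7.717, 3.508, 0.180), c(9.349, 3.760, 0.180),
                  c(4.673, 4.072, 0.043)),
    ties = c("2" = 1), years = 1934:2018, births = 3.5e6
  ),
  "EU5-Model1" = list(
    family = "model1", alpha = 0.0027, beta = c(-1.510, -0.068),
    excess = list(c(4.582, 3.473, 0.133), c(17.538, 3.782, 0.133),
                  c(15.667, 4.088, 0.099)),
    ties = c("2" = 1), years = 1950:2018, births = 3.0e6
  ),
  "EU5-Model2" = list(
    family = "model2", beta = c(-1.714, -0.056, -2.2e-04, 3.8e-06),
    excess = list(c(3.583, 3.470, 0.127), c(12.830, 3.770, 0.127),
                  c(7.672, 4.071, 0.087)),
    ties = c("2" = 1), years = 1950:2018, births = 3.0e6
  ),
  "UK" = list(
    family = "model1", alpha = 0.0026, beta = c(-2.590, -0.046),
    excess = list(c(4.969, 3.534, 0.124), c(16.551, 3.817, 0.124),
                  c(11.147, 4.055, 0.034)),
    ties = c("2" = 1), years = 1950:2018, births = 8.0e5
  ),
  "Germany" = list(
    family = "model1", alpha = 0.0029, beta = c(-1.261, -0.077),
    excess = list(c(4.998, 3.439, 0.098), c(20.390, 3.761, 0.098),
                  c(25.120, 4.044, 0.156)),
    ties = c("2" = 1), years = 1950:2018, births = 9.0e5
  ),
  "France" = list(
    family = "model1", alpha = 0.0029, beta = c(-1.457, -0.074),
    excess = list(c(5.667, 3.611, 0.098), c(10.910, 3.787, 0.098),
                  c(28.190, 4.094, 0.098)),
    ties = c("2" = 1, "3" = 1), years = 1950:2018, births = 8.0e5
  ),
  "Italy" = list(
    family = "model1", alpha = 0.0019, beta = c(-1.306, -0.067),
    excess = list(c(6.158, 3.469, 0.133), c(18.424, 3.759, 0.133),
                  c(17.280, 4.103, 0.127)),
    ties = c("2" = 1), years = 1950:2018, births = 8.0e5
  ),
  "Spain" = list(
    family = "model1", alpha = 0.0015, beta = c(-1.346, -0.063),
    excess = list(c(3.875, 3.394, 0.121), c(11.288, 3.649, 0.121),
                  c(2.888, 3.865, 0.053)),
    ties = c("2" = 1), years = 1950:2018, births = 6.0e5
  )
)

#' Available reference parameter sources
#'
#' @return Character vector of source identifiers accepted by
#'   [reference_spec()], [reference_params()] and [make_reference_fixture()].
#' @export
reference_sources <- function() names(.reference_table)

.reference_entry <- function(source) {
  entry <- .reference_table[[source]]
  if (is.null(entry)) {
    stop("unknown reference source '", source, "'; see reference_sources()")
  }
  entry
}

#' Model specification matching a published reference fit
#'
#' @param source One of [reference_sources()], e.g. `"EU5-Model1"` (pooled
#'   UK + Germany + France + Italy + Spain) or a single-country identifier.
#' @return A [model_spec()].
#' @export
reference_spec <- function(source) {
  entry <- .reference_entry(source)
  model_spec(entry$family, n_excess = length(entry$excess),
             width_ties = entry$ties)
}

#' Published parameter estimates as a parameter set
#'
#' Returns the reference estimates (trend coefficients and lognormal
#' excess-term triples) for a published fit, for use as fixture constants in
#' exact-recovery tests and peak-timing arithmetic.
#'
#' @inheritParams reference_spec
#' @return A [param_set()].
#' @export
reference_params <- function(source) {
  entry <- .reference_entry(source)
  param_set(reference_spec(source),
            alpha = entry$alpha %||% NA_real_,
            beta = entry$beta, excess = entry$excess)
}

#' Noise-free series generated from published estimates
#'
#' Evaluates the reference model on its published year range and converts
#' rates to counts with `deaths = round(rate * births)` (rounding, not
#' truncation, for a symmetric error bound of at most `1/births` on the
#' rate). The result is a deterministic series whose only departure from the
#' reference curve is integer rounding; fitting the generating specification
#' to it must recover the generating parameters.
#'
#' @inheritParams reference_spec
#' @param births Annual live births (single value recycled, or one per
#'   year); defaults to a realistic magnitude for the source.
#' @param years Calendar years; defaults to the source's published range.
#' @return A `mortality_series`.
#' @export
make_reference_fixture <- function(source, births = NULL, years = NULL) {
  entry <- .reference_entry(source)
  spec <- reference_spec(source)
  params <- reference_params(source)
  years <- if (is.null(years)) entry$years else as.integer(years)
  births <- if (is.null(births)) entry$births else births
  births <- rep_len(births, length(years))
  t <- years - spec$time_origin
  rate <- eval_rate(t, params, spec)
  if (any(rate <= 0 | rate >= 1)) {
    stop("reference rate outside (0,1) in year(s): ",
         paste(years[rate <= 0 | rate >= 1], collapse = ", "))
  }
  mortality_series(years, births, round(rate * births),
                   origin = spec$time_origin)
}
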