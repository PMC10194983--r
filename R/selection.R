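#' Overdispersion-scaled F-test between nested fits
#'
#' Compares a reduced model (deviance `dev0`) with a refined model (deviance
#' `dev1`, residual df `df2`) that adds `df1` free parameters. The test
#' statistic divides the per-parameter deviance drop by the refined model's
#' overdispersion: `F = (dev0 - dev1) / df1 / OD` with `OD = dev1 / df2`,
#' referred to the upper tail of `F(df1, df2)`. Scaling by OD makes the test
#' valid when the counts are far more variable than binomial sampling alone
#' would imply.
#'
#' @param dev0 Deviance of the reduced model.
#' @param dev1 Deviance of the refined model.
#' @param df1 Number of parameters added by the refinement.
#' @param df2 Residual degrees of freedom of the refined model.
#' @return A one-row tibble of class `model_comparison` with columns `dev0`,
#'   `dev1`, `df1`, `df2`, `od`, `fvalue`, `pvalue`.
#' @export
#' @examples
#' f_test(3244, 2363, df1 = 3, df2 = 76) # F about 9.44
f_test <- function(dev0, dev1, df1, df2) {
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be positive")
  if (dev0 < 0 || dev1 < 0) stop("deviances must be non-negative")
  od <- dev1 / df2
  if (dev1 > dev0) {
    warning("refined deviance exceeds reduced deviance; reporting F = 0")
    fv <- 0
  } else {
    fv <- (dev0 - dev1) / df1 / od
  }
  pv <- if (fv == 0) 1 else stats::pf(fv, df1, df2, lower.tail = FALSE)
  out <- tibble::tibble(dev0 = dev0, dev1 = dev1, df1 = as.integer(df1),
                        df2 = as.integer(df2), od = od, fvalue = fv, pvalue = pv)
  class(out) <- c("model_comparison", class(out))
  out
}

#' Stepwise addition of excess terms
#'
#' Fits the base family with 0, 1, ..., `max_terms` excess terms. Each step
#' starts from the previous fit's parameters and seeds one new term from the
#' largest positive link-scale residual of the current fit, then refits
#' everything. Successive fits are compared with [f_test()]. All steps are
#' fitted and reported; stopping is a reporting matter (inspect the p-value
#' column), never applied silently.
#'
#' Width ties in `base_spec` are activated at the step where both the tied
#' term and its master exist.
#'
#' @param series A `mortality_series`.
#' @param base_spec A [model_spec()] whose `n_excess` gives the target number
#'   of terms (overridden by `max_terms` if smaller).
#' @param max_terms Largest number of excess terms to fit (<= 5).
#' @return A list with `fits` (list of `excess_fit`, element `k + 1` has `k`
#'   terms; failed steps are `NULL`) and `comparisons` (tibble with one
#'   [f_test()] row per successful refinement, plus the term counts).
#' @export
stepwise_fit <- function(series, base_spec, max_terms = base_spec$n_excess) {
  stopifnot(max_terms <= 5, max_terms >= 0)
  spec_k <- function(k) {
    ties <- base_spec$width_ties
    ties <- ties[as.integer(names(ties)) <= k & ties <= k]
    fam <- base_spec$family
    if (fam == "model3" && k == 0) fam <- "model2" # war-time bell needs a term
    model_spec(fam, n_excess = k,
               width_ties = if (length(ties)) ties else NULL,
               interventions = if (nrow(base_spec$interventions))
                 base_spec$interventions else NULL,
               ww2_term = if (fam == "model3") min(base_spec$ww2_term, k) else 0L,
               time_origin = base_spec$time_origin)
  }
  fits <- vector("list", max_terms + 1L)
  comparisons <- list()
  prev <- NULL
  for (k in 0:max_terms) {
    sk <- spec_k(k)
    # hedge between warm-starting from the previous fit plus one new bell and
    # a fresh multistart; keep whichever ends at the lower deviance
    f_warm <- if (k > 0 && !is.null(prev)) {
      tryCatch(suppressWarnings(
        fit_model(series, sk, init = add_term_init(series, prev, sk))
      ), error = function(e) NULL)
    } else NULL
    f_auto <- tryCatch(suppressWarnings(fit_model(series, sk)),
                       error = function(e) NULL)
    cand_fits <- Filter(Negate(is.null), list(f_warm, f_auto))
    if (!length(cand_fits)) {
      warning("step with ", k, " term(s) failed")
      fits[k + 1L] <- list(NULL)
    } else {
      fits[[k + 1L]] <- cand_fits[[which.min(vapply(cand_fits,
        function(f) f$deviance, numeric(1)))]]
    }
    if (!is.null(prev) && !is.null(fits[[k + 1L]])) {
      cmp <- f_test(prev$deviance, fits[[k + 1L]]$deviance,
                    df1 = prev$df - fits[[k + 1L]]$df,
                    df2 = fits[[k + 1L]]$df)
      cmp$terms_from <- k - 1L
      cmp$terms_to <- k
      comparisons[[length(comparisons) + 1L]] <- cmp
    }
    if (!is.null(fits[[k + 1L]])) prev <- fits[[k + 1L]]
  }
  list(fits = fits, comparisons = purrr::list_rbind(comparisons))
}

# Seed a (k)-term initialisation from a fitted (k-1)-term model: keep the
# fitted terms, place one new bell at the largest positive link-scale
# residual, and order terms by location.
add_term_init <- function(series, prev_fit, new_spec) {
  t <- series$year - new_spec$time_origin
  obs <- pmin(pmax(series$rate, 1e-10), 1 - 1e-10)
  p <- prev_fit$params
  if (new_spec$family == "model1") {
    eta_obs <- stats::qlogis(pmin(pmax((obs - p$alpha) / (1 - p$alpha), 1e-10),
                                  1 - 1e-10))
    eta_fit <- linear_predictor(t, p, prev_fit$spec)
  } else {
    eta_obs <- log(obs)
    eta_fit <- linear_predictor(t, p, prev_fit$spec)
  }
  resid <- eta_obs - eta_fit
  i_star <- which.max(resid)
  h <- max(resid[i_star], 1e-3)
  new_term <- c(a = h * t[i_star], mu = log(t[i_star]), sigma = 0.15)
  ex <- rbind(as.matrix(p$excess), new_term)
  ex <- ex[order(ex[, "mu"]), , drop = FALSE]
  param_set(new_spec,
            alpha = if (new_spec$family == "model1") p$alpha else NA_real_,
            beta = p$beta[seq_len(if (new_spec$family == "model1") 2 else 4)],
            excess = as.data.frame(ex), iv = p$iv)
}

# Root-finder shared by profile_ci: walks outward from the estimate until the
# profiled objective crosses dev_hat + thresh, then bisects with uniroot.
# pdev_fn(v) must return the profiled deviance at fixed value v.
.profile_bound <- function(pdev_fn, hat, se, dev_hat, thresh,
                           direction = c(-1, 1), max_se = 10) {
  direction <- direction[1]
  g <- function(v) pdev_fn(v) - dev_hat - thresh
  step <- 1.5 * se
  v_in <- hat
  g_in <- -thresh
  repeat {
    v_out <- v_in + direction * step
    if (abs(v_out - hat) > max_se * se) {
      warning("profile failed to bracket within ", max_se,
              " SE; returning the bound reached (open interval)")
      return(structure(v_out, open = TRUE))
    }
    g_out <- g(v_out)
    if (is.finite(g_out) && g_out > 0) break
    v_in <- v_out
    if (is.finite(g_out)) g_in <- g_out
    step <- step * 1.6
  }
  interval <- sort(c(v_in, v_out))
  stats::uniroot(g, interval = interval, tol = max(se * 1e-5, 1e-12))$root
}

#' Profile confidence interval for a single parameter
#'
#' Fixes the parameter on a grid of trial values, re-optimises all other
#' parameters at each, and returns the values where the profiled weighted
#' deviance exceeds its minimum by `OD * qF(level; 1, df2)` — the
#' overdispersion-scaled F threshold, with `df2` the residual df of the full
#' fit. Deterministic (monotone outward bracketing followed by root
#' bisection). In a linear-model limit the interval coincides with the Wald
#' interval.
#'
#' @inheritParams fit_model
#' @param fit The converged full `excess_fit`.
#' @param param Free-parameter name to profile, e.g. `"beta2"`.
#' @param level Confidence level in `(0, 1)`, default 0.90.
#' @param max_se Bracket search limit in units of the Wald SE (default 10);
#'   beyond it an open-interval warning is issued.
#' @return Numeric `c(lower, upper)` with attributes `level` and `param`.
#' @export
profile_ci <- function(series, spec, fit, param, level = 0.90, max_se = 10) {
  stopifnot(inherits(fit, "excess_fit"), level > 0, level < 1)
  if (!param %in% fit$free) stop("'", param, "' is not a free parameter of the fit")
  hat <- fit$estimate[[param]]
  se <- fit$se[[param]]
  thresh <- fit$overdispersion * stats::qf(level, 1, fit$df)
  pdev <- function(v) {
    refit <- suppressWarnings(fit_model(
      series, spec, init = fit$params,
      fixed = c(stats::setNames(v, param), fit$fixed)
    ))
    refit$deviance
  }
  lower <- .profile_bound(pdev, hat, se, fit$deviance, thresh, direction = -1,
                          max_se = max_se)
  upper <- .profile_bound(pdev, hat, se, fit$deviance, thresh, direction = 1,
                          max_se = max_se)
  structure(c(lower = as.numeric(lower), upper = as.numeric(upper)),
            level = level, param = param)
}
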