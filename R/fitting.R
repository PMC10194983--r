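#' Binomial-variance weighted deviance and standardized residuals
#'
#' The deviance used throughout is the Pearson-type weighted residual sum of
#' squares: each residual is standardized by the binomial standard deviation
#' `sqrt(fit * (1 - fit) / births)` implied by the fitted rate, and the
#' deviance is the sum of squared standardized residuals. Overdispersion is
#' this deviance divided by the residual degrees of freedom.
#'
#' @param observed Observed per-year proportions.
#' @param fitted Fitted per-year proportions, strictly inside `(0, 1)`.
#' @param births Per-year live-birth counts (the binomial denominators).
#' @return A list with elements `deviance` (scalar) and `residuals`
#'   (standardized residuals, one per year).
#' @export
#' @examples
#' deviance_and_residuals(0.011, 0.010, 1e6) # residual about 10.05
deviance_and_residuals <- function(observed, fitted, births) {
  stopifnot(length(observed) == length(fitted), length(observed) == length(births))
  if (any(fitted <= 0 | fitted >= 1)) {
    stop("fitted rates must lie strictly inside (0, 1); binomial variance undefined")
  }
  if (any(births < 1)) stop("births must be >= 1")
  v <- fitted * (1 - fitted) / births
  r <- (observed - fitted) / sqrt(v)
  list(deviance = sum(r^2), residuals = r)
}

# Bounds for the free-parameter vector: widths bounded away from zero,
# the rate floor confined to [0, min observed rate].
.param_bounds <- function(nm, series) {
  lower <- stats::setNames(rep(-Inf, length(nm)), nm)
  upper <- stats::setNames(rep(Inf, length(nm)), nm)
  lower[grepl("^sigma", nm)] <- 1e-3
  if ("alpha" %in% nm) {
    lower[["alpha"]] <- 0
    upper[["alpha"]] <- min(series$rate)
  }
  list(lower = lower, upper = upper)
}

#' Fit a trend-plus-excess model by reweighted nonlinear least squares
#'
#' Minimises the binomial-variance weighted residual sum of squares
#' `sum((obs - fit)^2 / (fit (1 - fit) / births))`. By default the weights
#' are fully iterated: an inner Levenberg-Marquardt solve uses variances
#' frozen at the current fitted values, the variances are then recomputed and
#' the solve repeated until the relative deviance change falls below `tol`
#' (or `max_outer` cycles). `weights = "one_shot"` instead freezes the
#' variances once (from the observed rates) and performs a single inner
#' solve, which is occasionally useful for sensitivity checks and gives a
#' fixed, externally reproducible objective.
#'
#' Standard errors come from the unscaled weighted Jacobian covariance
#' `(J'J)^-1` (the binomial variance is treated as known); set
#' `od_scale_se = TRUE` to inflate them by the square root of the estimated
#' overdispersion.
#'
#' @param series A `mortality_series`.
#' @param spec A [model_spec()].
#' @param init Starting [param_set()], or `NULL` for the deterministic staged
#'   initialisation of [initialize_parameters()].
#' @param fixed Optional named numeric vector of parameters held fixed (by
#'   free-parameter name, e.g. `c(beta2 = -0.07)`); fixed parameters are
#'   excluded from the free set and from the degrees-of-freedom count.
#' @param weights `"iterated"` (default) or `"one_shot"`.
#' @param max_outer Maximum reweighting cycles (default 25).
#' @param tol Relative deviance change declaring convergence (default 1e-8).
#' @param od_scale_se Scale standard errors by `sqrt(overdispersion)`?
#'   Default `FALSE`.
#' @return An object of class `excess_fit`: parameter estimates with standard
#'   errors and t-values, fitted rates and variances, standardized residuals,
#'   deviance, residual df, overdispersion, convergence information and the
#'   free-parameter covariance matrix.
#' @export
fit_model <- function(series, spec, init = NULL, fixed = NULL,
                      weights = c("iterated", "one_shot"),
                      max_outer = 25L, tol = 1e-8, od_scale_se = FALSE) {
  weights <- match.arg(weights)
  if (!is.null(init)) {
    return(.fit_model_one(series, spec, init, fixed, weights, max_outer, tol,
                          od_scale_se))
  }
  # automatic start: polish the top-ranked candidate placements and keep the
  # best-deviance fit (local minima are a real hazard with overlapping bells)
  cands <- .candidate_inits(series, spec, n_keep = 3L)
  best <- NULL
  first_cond <- NULL
  for (cand in cands) {
    res <- tryCatch(
      withCallingHandlers(
        .fit_model_one(series, spec, cand, fixed, weights, max_outer, tol,
                       od_scale_se),
        warning = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (is.null(first_cond)) first_cond <- res
      next
    }
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop(first_cond)
  if (!best$converged) {
    warning("reweighting did not converge; returning the last iterate")
  }
  best
}

.fit_model_one <- function(series, spec, init, fixed = NULL,
                           weights = c("iterated", "one_shot"),
                           max_outer = 25L, tol = 1e-8, od_scale_se = FALSE) {
  weights <- match.arg(weights)
  stopifnot(inherits(spec, "model_spec"))
  t <- series$year - spec$time_origin
  if (any(t < 1)) {
    stop("series contains years with t < 1 (before ", spec$time_origin + 1,
         "); exclude them or change the time origin")
  }
  obs <- series$rate
  lb <- series$births
  nm_all <- free_names(spec)
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% nm_all)) {
      stop("unknown fixed parameter(s): ",
           paste(setdiff(names(fixed), nm_all), collapse = ", "))
    }
  }
  nm <- setdiff(nm_all, names(fixed))
  if (length(nm) >= nrow(series)) {
    stop("free parameters (", length(nm), ") must be fewer than observations (",
         nrow(series), ")")
  }
  theta <- pack_params(init, spec)[nm]
  bounds <- .param_bounds(nm_all, series)
  theta <- pmin(pmax(theta, bounds$lower[nm]), bounds$upper[nm])

  rate_fn <- .compile_rate_fn(spec, t, nm, fixed)

  var_of <- function(rate) rate * (1 - rate) / lb
  cur_var <- if (weights == "one_shot") {
    var_of(pmin(pmax(obs, 1e-12), 1 - 1e-12))
  } else {
    r0 <- rate_fn(theta)
    if (any(r0 <= 0 | r0 >= 1)) var_of(pmin(pmax(obs, 1e-12), 1 - 1e-12))
    else var_of(r0)
  }

  dev_prev <- Inf
  n_iter <- 0L
  converged <- FALSE
  fit_lm <- NULL
  n_cycles <- if (weights == "one_shot") 1L else max_outer
  for (cycle in seq_len(n_cycles)) {
    n_iter <- cycle
    w <- 1 / sqrt(cur_var)
    resid_fn <- function(th) (obs - rate_fn(th)) * w
    fit_lm <- minpack.lm::nls.lm(
      par = theta, fn = resid_fn,
      lower = bounds$lower[nm], upper = bounds$upper[nm],
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    )
    theta <- stats::setNames(coef(fit_lm), nm)
    rate_hat <- rate_fn(theta)
    if (any(rate_hat <= 0 | rate_hat >= 1)) {
      warning("fitted rate outside (0,1); keeping previous weights")
      break
    }
    new_var <- var_of(rate_hat)
    dev_now <- sum((obs - rate_hat)^2 / new_var)
    if (weights == "one_shot") { converged <- TRUE; break }
    if (is.finite(dev_prev) &&
        abs(dev_prev - dev_now) <= tol * max(dev_prev, .Machine$double.eps)) {
      converged <- TRUE
      cur_var <- new_var
      break
    }
    dev_prev <- dev_now
    cur_var <- new_var
  }
  if (!converged) {
    warning("reweighting did not converge in ", n_iter,
            " cycle(s); returning the last iterate")
  }

  # canonical labelling: excess terms in time order (a pure relabelling of
  # the same curve; skipped if it would violate a width tie or a fixed value)
  theta <- .order_terms_theta(theta, spec, fixed)

  rate_hat <- rate_fn(theta)
  dr <- deviance_and_residuals(obs, rate_hat, lb)
  df <- nrow(series) - length(nm)
  if (df < 1) stop("non-positive residual degrees of freedom")
  od <- dr$deviance / df

  # covariance of the free parameters from the weighted Jacobian
  w <- 1 / sqrt(var_of(rate_hat))
  jac <- .num_jacobian(function(th) (obs - rate_fn(th)) * w, theta)
  jtj <- crossprod(jac)
  # column-equilibrate before inversion: polynomial and bell columns live on
  # wildly different scales and would otherwise defeat solve() numerically
  d <- sqrt(diag(jtj))
  if (any(d <= 0)) {
    stop("singular Jacobian; parameter(s) without leverage: ",
         paste(nm[d <= 0], collapse = ", "))
  }
  C <- jtj / tcrossprod(d)
  cov <- tryCatch(solve(C) / tcrossprod(d), error = function(e) NULL)
  if (is.null(cov)) {
    sv <- svd(C)
    flat <- nm[abs(sv$v[, ncol(sv$v)]) > 0.3]
    stop("singular Jacobian; near-collinear parameter(s): ",
         paste(if (length(flat)) flat else nm, collapse = ", "))
  }
  dimnames(cov) <- list(nm, nm)
  if (od_scale_se) cov <- cov * od
  se <- sqrt(pmax(diag(cov), 0))

  structure(list(
    params = unpack_params(theta, spec, fixed),
    spec = spec, series = series,
    free = nm, estimate = theta, se = se, tvalues = theta / se,
    fixed = fixed,
    fitted = rate_hat, var = var_of(rate_hat), residuals = dr$residuals,
    deviance = dr$deviance, df = df, overdispersion = od,
    converged = converged, n_iter = n_iter, cov = cov,
    od_scaled_se = od_scale_se
  ), class = "excess_fit")
}

# Relabel excess terms so locations are increasing. Values only move between
# symmetric slots, so the fitted curve is unchanged; returns the input when a
# term parameter is fixed or the permutation would break a width tie.
.order_terms_theta <- function(theta, spec, fixed = NULL) {
  K <- spec$n_excess
  if (K < 2) return(theta)
  term_nm <- c(paste0("a", 1:K), paste0("mu", 1:K), paste0("sigma", 1:K))
  if (!is.null(fixed) && any(names(fixed) %in% term_nm)) return(theta)
  tied <- spec$width_ties
  master_of <- function(k) {
    kc <- as.character(k)
    if (kc %in% names(tied)) tied[[kc]] else k
  }
  mus <- vapply(1:K, function(k) theta[[paste0("mu", k)]], numeric(1))
  ord <- order(mus)
  if (identical(ord, 1:K)) return(theta)
  sig_vals <- vapply(1:K, function(k) theta[[paste0("sigma", master_of(k))]],
                     numeric(1))
  new_sig <- sig_vals[ord]
  for (kc in names(tied)) {
    if (abs(new_sig[as.integer(kc)] - new_sig[tied[[kc]]]) > 1e-12) {
      return(theta) # permutation incompatible with the tie structure
    }
  }
  out <- theta
  for (k in 1:K) {
    out[[paste0("a", k)]] <- theta[[paste0("a", ord[k])]]
    out[[paste0("mu", k)]] <- theta[[paste0("mu", ord[k])]]
    snm <- paste0("sigma", k)
    if (snm %in% names(theta)) out[[snm]] <- new_sig[k]
  }
  out
}

# Central-difference Jacobian of a vector-valued function.
.num_jacobian <- function(fn, theta, rel_step = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- rel_step * max(abs(theta[j]), 1e-4)
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

#' @export
print.excess_fit <- function(x, ...) {
  cat("<excess_fit> family:", x$spec$family, "| n =", nrow(x$series),
      "| free params:", length(x$free), "\n")
  cat(sprintf("  deviance = %.6g (df = %d), overdispersion = %.3g\n",
              x$deviance, x$df, x$overdispersion))
  if (!x$converged) cat("  WARNING: reweighting did not converge\n")
  print(generics::tidy(x), n = Inf)
  invisible(x)
}

#' Deterministic staged initialisation
#'
#' Stage one fits the trend-only family on the link scale (logit with a
#' provisional floor for `model1`, log for `model2`/`model3`). Stage two
#' places the excess terms by orthogonal matching pursuit on the link scale:
#' candidate bells on a fixed grid of log-time locations and a small set of
#' trial widths are added one at a time, each stage choosing the candidate
#' that minimises the link-scale residual sum of squares with the trend and
#' all amplitudes refit in closed form. The pursuit is repeated over a small
#' deterministic grid of trial widths (and provisional floors for `model1`),
#' and the best run is returned; [fit_model()] with `init = NULL` polishes
#' the top few runs in full and keeps the best-deviance result. Entirely
#' deterministic: repeated calls give identical output.
#'
#' @inheritParams fit_model
#' @return A [param_set()] suitable as `init` for [fit_model()].
#' @export
initialize_parameters <- function(series, spec) {
  .candidate_inits(series, spec, n_keep = 1L)[[1]]
}

# Ranked candidate initialisations (best link-scale pursuit first).
.candidate_inits <- function(series, spec, n_keep = 3L) {
  t <- series$year - spec$time_origin
  if (any(t < 1)) stop("initialisation requires t >= 1 for all years")
  obs <- pmin(pmax(series$rate, 1e-10), 1 - 1e-10)
  lt <- log(t)
  m1 <- spec$family == "model1"
  nb <- if (m1) 2L else 4L

  # trend design (plus intervention dummies) on the link scale
  X0 <- cbind(1, t)
  if (!m1) X0 <- cbind(X0, t^2, t^3)
  J <- nrow(spec$interventions)
  if (J) {
    yr <- t + spec$time_origin
    for (j in seq_len(J)) {
      y0 <- spec$interventions$year[j]
      X0 <- cbind(X0, if (spec$interventions$kind[j] == "pulse")
        as.numeric(yr == y0) else as.numeric(yr >= y0))
    }
  }

  alpha_grid <- if (m1) seq(0.3, 0.97, length.out = 8) * min(obs) else NA_real_
  sigma_grid <- c(0.06, 0.12, 0.2)
  mu_hi <- log(max(max(t) - 2, min(t) + 1))
  mu_grid <- seq(log(min(t)), mu_hi, by = 0.07)
  bell <- function(mu, sg) (1 / t) * exp(-(lt - mu)^2 / (2 * sg * sg))

  make_params <- function(alpha, cf, terms) {
    beta <- numeric(nb)
    beta[seq_len(nb)] <- cf[seq_len(nb)]
    param_set(spec, alpha = if (m1) alpha else NA_real_, beta = beta,
              excess = terms,
              iv = if (J) cf[nb + seq_len(J)] else numeric(0))
  }

  runs <- list()
  for (alpha in alpha_grid) {
    z <- if (m1) {
      stats::qlogis(pmin(pmax((obs - alpha) / (1 - alpha), 1e-10), 1 - 1e-10))
    } else {
      log(obs)
    }
    # delta-method variance of the link-scale observation under binomial noise
    wz <- if (m1) {
      u <- pmin(pmax((obs - alpha) / (1 - alpha), 1e-10), 1 - 1e-10)
      series$births * (u * (1 - u) * (1 - alpha))^2 / (obs * (1 - obs))
    } else {
      series$births * obs^2 / (obs * (1 - obs))
    }
    wfit <- function(X) stats::lm.wfit(X, z, wz)
    wsse <- function(f) sum(wz * f$residuals^2)
    if (spec$n_excess == 0L) {
      f0 <- wfit(X0)
      runs[[length(runs) + 1L]] <- list(
        sse = wsse(f0), key = paste0("trend", signif(alpha, 3)),
        params = make_params(alpha, f0$coefficients,
                             tibble::tibble(a = numeric(), mu = numeric(),
                                            sigma = numeric())))
      next
    }
    n_bell0 <- ncol(X0)
    for (sg0 in sigma_grid) {
      chosen_mu <- numeric(0)
      chosen_sg <- numeric(0)
      X <- X0
      for (k in seq_len(spec$n_excess)) {
        best <- NULL
        best_any <- NULL
        for (mu in mu_grid) {
          if (length(chosen_mu) && any(abs(mu - chosen_mu) < 0.1)) next
          fitk <- wfit(cbind(X, bell(mu, sg0)))
          sse <- wsse(fitk)
          amps_k <- fitk$coefficients[-seq_len(n_bell0)]
          if (is.null(best_any) || sse < best_any$sse) {
            best_any <- list(mu = mu, sse = sse)
          }
          # prefer placements where every bell keeps a positive amplitude
          if (all(amps_k > 0) && (is.null(best) || sse < best$sse)) {
            best <- list(mu = mu, sse = sse)
          }
        }
        if (is.null(best)) best <- best_any
        if (is.null(best)) break
        chosen_mu <- c(chosen_mu, best$mu)
        chosen_sg <- c(chosen_sg, sg0)
        X <- cbind(X, bell(best$mu, sg0))
      }
      if (length(chosen_mu) < spec$n_excess) next
      fit_all <- wfit(X)
      ord <- order(chosen_mu)
      amps <- fit_all$coefficients[n_bell0 + seq_len(spec$n_excess)]
      terms <- tibble::tibble(a = amps[ord], mu = chosen_mu[ord],
                              sigma = chosen_sg[ord])
      runs[[length(runs) + 1L]] <- list(
        sse = wsse(fit_all),
        key = paste(round(sort(chosen_mu), 2), collapse = ","),
        params = make_params(alpha, fit_all$coefficients, terms))
    }
  }
  if (!length(runs)) stop("initialisation failed: no candidate placement found")
  runs <- runs[order(vapply(runs, function(r) r$sse, numeric(1)))]
  # keep the best run per distinct location set
  seen <- character(0)
  out <- list()
  for (r in runs) {
    if (r$key %in% seen) next
    seen <- c(seen, r$key)
    out[[length(out) + 1L]] <- r$params
    if (length(out) >= n_keep) break
  }
  out
}

#' Poisson log-linear trend fit with optional window exclusion
#'
#' Count-likelihood log-linear regression of deaths on a polynomial time
#' trend with a log-births offset — the classical extrapolation /
#' interpolation approach to excess estimation. When `exclude_window` is
#' given, those years are left out of the fit and predictions over them (and
#' everywhere else) are returned, so observed-minus-predicted sums over the
#' window estimate its excess.
#'
#' @param series A `mortality_series`.
#' @param degree Polynomial degree of the time trend, 1, 2 or 3.
#' @param exclude_window Optional `c(first_year, last_year)` left out of the
#'   regression.
#' @param origin Time origin; defaults to the series' origin.
#' @return An object of class `loglinear_fit` with the underlying `glm`, the
#'   coefficient table and a per-year tibble of observed and predicted rates
#'   and deaths (`excluded` flags the window years).
#' @export
fit_loglinear_trend <- function(series, degree = 2, exclude_window = NULL,
                                origin = NULL) {
  stopifnot(degree %in% 1:3)
  origin <- origin %||% attr(series, "origin") %||% 1930
  df <- tibble::as_tibble(series)
  df$t <- df$year - origin
  df$excluded <- FALSE
  if (!is.null(exclude_window)) {
    df$excluded <- df$year >= exclude_window[1] & df$year <= exclude_window[2]
  }
  keep <- df[!df$excluded, ]
  if (nrow(keep) < degree + 2) {
    stop("need at least ", degree + 2, " retained observations for degree ", degree)
  }
  fml <- switch(degree,
                deaths ~ t + offset(log(births)),
                deaths ~ t + I(t^2) + offset(log(births)),
                deaths ~ t + I(t^2) + I(t^3) + offset(log(births)))
  gm <- stats::glm(fml, family = stats::poisson(), data = keep)
  df$fitted_deaths <- exp(stats::predict(gm, newdata = df))
  df$fitted_rate <- df$fitted_deaths / df$births
  structure(list(model = gm, degree = degree, exclude_window = exclude_window,
                 table = df),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat("<loglinear_fit> Poisson trend, degree", x$degree, "\n")
  if (!is.null(x$exclude_window)) {
    cat("  excluded window:", x$exclude_window[1], "-", x$exclude_window[2], "\n")
  }
  print(stats::coef(summary(x$model)))
  invisible(x)
}
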