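#' Declare a trend-plus-excess model structure
#'
#' Three trend families are supported:
#' * `model1` — floored logistic: `rate = alpha + (1 - alpha) * plogis(eta)`
#'   with a linear time trend in the linear predictor `eta`;
#' * `model2` — exponential trend with a cubic time polynomial:
#'   `rate = exp(eta)`, `eta = beta1 + beta2 t + beta3 t^2 + beta4 t^3`;
#' * `model3` — the `model2` trend with one excess term designated as a
#'   war-time bell, so that pre-1950 disruption is absorbed by the model
#'   rather than by truncating the series.
#'
#' Any number of lognormal-density excess terms `(a/t) exp(-(log t - mu)^2 /
#' (2 sigma^2))` can be added to `eta`, optionally with width ties (two terms
#' sharing one sigma, the "equal half-widths" constraint), plus intervention
#' dummies (a single-year pulse or a level-shift step) for definitional breaks
#' such as the 1994 stillbirth registration change.
#'
#' @param family `"model1"`, `"model2"` or `"model3"`.
#' @param n_excess Number of lognormal excess terms (>= 0). For `model3` this
#'   count includes the designated war-time term.
#' @param width_ties Named integer vector mapping a tied term index to its
#'   master index, e.g. `c("2" = 1)` forces term 2's width to equal term 1's.
#'   Ties must point backwards (tied index > master index).
#' @param interventions Optional tibble/data frame with columns `kind`
#'   (`"pulse"` or `"step"`) and `year` (the pulse year, or the first year of
#'   the step).
#' @param ww2_term For `model3`, index of the excess term treated as the
#'   war-time bell (default 1, the earliest term).
#' @param time_origin Calendar year of `t = 0`; default 1930.
#'
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("model1", n_excess = 3, width_ties = c("2" = 1))
model_spec <- function(family = c("model1", "model2", "model3"),
                       n_excess = 0L,
                       width_ties = NULL,
                       interventions = NULL,
                       ww2_term = if (match.arg(family) == "model3") 1L else 0L,
                       time_origin = 1930L) {
  family <- match.arg(family)
  n_excess <- as.integer(n_excess)
  stopifnot(n_excess >= 0L)
  ties <- integer(0)
  if (!is.null(width_ties) && length(width_ties)) {
    ties <- as.integer(width_ties)
    names(ties) <- names(width_ties)
    tied_idx <- as.integer(names(ties))
    if (anyNA(tied_idx)) stop("width_ties must have integer names (tied term index)")
    if (any(tied_idx <= ties)) stop("tied index must be greater than its master index")
    if (any(tied_idx > n_excess) || any(ties < 1L)) {
      stop("width tie indices must lie in 1..n_excess")
    }
    if (any(as.character(ties) %in% names(ties))) {
      stop("chained width ties are not allowed; tie every follower to the free master")
    }
  }
  iv <- tibble::tibble(kind = character(), year = integer())
  if (!is.null(interventions) && nrow(interventions)) {
    iv <- tibble::as_tibble(interventions)
    stopifnot(all(c("kind", "year") %in% names(iv)))
    iv$kind <- match.arg(iv$kind, c("pulse", "step"), several.ok = TRUE)
    iv$year <- as.integer(iv$year)
  }
  ww2_term <- as.integer(ww2_term)
  if (family == "model3") {
    if (ww2_term < 1L || ww2_term > n_excess) {
      stop("model3 requires a designated war-time excess term (1 <= ww2_term <= n_excess)")
    }
  } else {
    ww2_term <- 0L
  }
  structure(
    list(family = family, n_excess = n_excess, width_ties = ties,
         interventions = iv, ww2_term = ww2_term,
         time_origin = as.integer(time_origin)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> family:", x$family,
      "| excess terms:", x$n_excess, sep = " ")
  if (length(x$width_ties)) {
    cat(" | ties:", paste0(names(x$width_ties), "->", x$width_ties, collapse = ", "))
  }
  if (nrow(x$interventions)) {
    cat(" | interventions:", paste0(x$interventions$kind, "@", x$interventions$year,
                                    collapse = ", "))
  }
  if (x$ww2_term > 0) cat(" | war-time term:", x$ww2_term)
  cat("\n")
  invisible(x)
}

#' Assemble a full parameter set for a model specification
#'
#' The parameter set is the single home of all model coefficients: the rate
#' floor `alpha` (model1 only), the polynomial trend coefficients
#' `beta1..beta4` (`beta3 = beta4 = 0` structurally under model1), one
#' `(a, mu, sigma)` triple per excess term (amplitude, log-time location,
#' log-time width), and one coefficient per intervention dummy.
#'
#' @param spec A [model_spec()].
#' @param alpha Rate floor in `[0, 1)`; required for `model1`, ignored
#'   otherwise.
#' @param beta Numeric vector of trend coefficients: `c(beta1, beta2)` for
#'   `model1`, `c(beta1, beta2, beta3, beta4)` for `model2`/`model3`.
#' @param excess Excess-term triples: a list of length-3 numeric vectors
#'   `c(a, mu, sigma)`, or a data frame with columns `a`, `mu`, `sigma`; one
#'   entry per term in `spec`. Tied widths are overwritten with their
#'   master's value.
#' @param iv Intervention coefficients, one per row of `spec$interventions`.
#'
#' @return An object of class `param_set`.
#' @export
param_set <- function(spec, alpha = NA_real_, beta = numeric(), excess = NULL,
                      iv = numeric()) {
  stopifnot(inherits(spec, "model_spec"))
  nb <- if (spec$family == "model1") 2L else 4L
  if (length(beta) < nb) stop("need ", nb, " trend coefficients for ", spec$family)
  beta_full <- c(beta1 = 0, beta2 = 0, beta3 = 0, beta4 = 0)
  beta_full[seq_len(nb)] <- as.numeric(beta[seq_len(nb)])
  if (spec$family == "model1") {
    if (!is.finite(alpha) || alpha < 0 || alpha >= 1) {
      stop("model1 requires a rate floor alpha in [0, 1)")
    }
  } else {
    alpha <- NA_real_
  }
  if (is.null(excess)) excess <- list()
  if (is.data.frame(excess)) {
    ex <- tibble::as_tibble(excess)[, c("a", "mu", "sigma")]
  } else {
    ex <- purrr::map(excess, function(v) {
      tibble::tibble(a = v[[1]], mu = v[[2]], sigma = v[[3]])
    }) |> purrr::list_rbind()
    if (!nrow(ex)) ex <- tibble::tibble(a = numeric(), mu = numeric(), sigma = numeric())
  }
  if (nrow(ex) != spec$n_excess) {
    stop("expected ", spec$n_excess, " excess term(s), got ", nrow(ex))
  }
  for (tied in names(spec$width_ties)) {
    ex$sigma[as.integer(tied)] <- ex$sigma[spec$width_ties[[tied]]]
  }
  if (nrow(ex) && any(ex$sigma <= 0 & !seq_len(nrow(ex)) %in% as.integer(names(spec$width_ties)))) {
    stop("excess widths (sigma) must be positive")
  }
  iv <- as.numeric(iv)
  if (length(iv) != nrow(spec$interventions)) {
    if (length(iv) == 0) iv <- rep(0, nrow(spec$interventions))
    else stop("need one coefficient per intervention")
  }
  structure(list(alpha = alpha, beta = beta_full, excess = ex, iv = iv,
                 family = spec$family),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>", x$family, "\n")
  if (is.finite(x$alpha)) cat("  alpha =", format(x$alpha), "\n")
  nb <- if (x$family == "model1") 2 else 4
  cat("  beta  =", paste(format(x$beta[seq_len(nb)], digits = 4), collapse = ", "), "\n")
  if (nrow(x$excess)) {
    cat("  excess terms (a, mu, sigma):\n")
    for (k in seq_len(nrow(x$excess))) {
      cat("   ", k, ":", paste(format(unlist(x$excess[k, ]), digits = 4), collapse = ", "), "\n")
    }
  }
  if (length(x$iv)) cat("  interventions =", paste(format(x$iv, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# ---- free-parameter bookkeeping ------------------------------------------

#' Names of the free parameters implied by a model specification
#'
#' Tied widths and structurally-zero polynomial coefficients are not free;
#' the residual degrees of freedom of a fit are `n_obs - length(free_names())`.
#'
#' @param spec A [model_spec()].
#' @return Character vector of free-parameter names in canonical order.
#' @export
free_names <- function(spec) {
  nm <- if (spec$family == "model1") c("alpha", "beta1", "beta2")
        else c("beta1", "beta2", "beta3", "beta4")
  tied <- as.integer(names(spec$width_ties))
  for (k in seq_len(spec$n_excess)) {
    nm <- c(nm, paste0("a", k), paste0("mu", k))
    if (!k %in% tied) nm <- c(nm, paste0("sigma", k))
  }
  if (nrow(spec$interventions)) nm <- c(nm, paste0("iv", seq_len(nrow(spec$interventions))))
  nm
}

#' Number of free parameters of a model specification
#'
#' @inheritParams free_names
#' @return Integer count of free parameters.
#' @export
n_free_params <- function(spec) length(free_names(spec))

# Pack a param_set into the free-parameter vector.
pack_params <- function(params, spec) {
  nm <- free_names(spec)
  th <- stats::setNames(numeric(length(nm)), nm)
  for (n in nm) {
    th[[n]] <- switch(substr(n, 1, 2),
      al = params$alpha,
      be = params$beta[[n]],
      a1 = , a2 = , a3 = , a4 = , a5 = params$excess$a[[as.integer(substring(n, 2))]],
      mu = params$excess$mu[[as.integer(substring(n, 3))]],
      si = params$excess$sigma[[as.integer(substring(n, 6))]],
      iv = params$iv[[as.integer(substring(n, 3))]],
      stop("unknown parameter name: ", n)
    )
  }
  th
}

# Rebuild a full param_set from a free vector plus optional fixed overrides.
unpack_params <- function(theta, spec, fixed = NULL) {
  full <- c(theta, fixed)
  get0_ <- function(n) if (n %in% names(full)) full[[n]] else 0
  alpha <- if (spec$family == "model1") full[["alpha"]] else NA_real_
  beta <- c(beta1 = get0_("beta1"), beta2 = get0_("beta2"),
            beta3 = get0_("beta3"), beta4 = get0_("beta4"))
  ex <- tibble::tibble(a = numeric(spec$n_excess), mu = numeric(spec$n_excess),
                       sigma = numeric(spec$n_excess))
  tied <- spec$width_ties
  for (k in seq_len(spec$n_excess)) {
    ex$a[k] <- full[[paste0("a", k)]]
    ex$mu[k] <- full[[paste0("mu", k)]]
    kc <- as.character(k)
    ex$sigma[k] <- if (kc %in% names(tied)) NA_real_ else full[[paste0("sigma", k)]]
  }
  for (kc in names(tied)) ex$sigma[as.integer(kc)] <- ex$sigma[tied[[kc]]]
  iv <- if (nrow(spec$interventions)) {
    vapply(seq_len(nrow(spec$interventions)),
           function(j) full[[paste0("iv", j)]], numeric(1))
  } else numeric(0)
  structure(list(alpha = alpha, beta = beta, excess = ex, iv = iv,
                 family = spec$family),
            class = "param_set")
}
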