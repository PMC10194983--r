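# Internal fast evaluator used inside optimisation loops. Works directly on
# the free-parameter vector (by position, robust to name stripping inside the
# optimiser) with precomputed time powers and tie-resolved symbol maps,
# avoiding per-call param_set allocation.
.compile_rate_fn <- function(spec, t, nm, fixed = NULL) {
  m1 <- spec$family == "model1"
  lt <- log(t); t2 <- t^2; t3 <- t^3
  K <- spec$n_excess
  tied <- spec$width_ties
  J <- nrow(spec$interventions)
  Z <- if (J) lapply(seq_len(J), function(j) {
    y0 <- spec$interventions$year[j]
    yr <- t + spec$time_origin
    if (spec$interventions$kind[j] == "pulse") as.numeric(yr == y0)
    else as.numeric(yr >= y0)
  }) else list()

  resolve <- function(name) {
    # returns c(free_index or NA, fixed/structural value)
    i <- match(name, nm)
    if (!is.na(i)) return(c(i, NA_real_))
    if (!is.null(fixed) && name %in% names(fixed)) return(c(NA_real_, fixed[[name]]))
    c(NA_real_, 0) # structural zero (beta3/beta4 under model1)
  }
  sig_name <- vapply(seq_len(K), function(k) {
    kc <- as.character(k)
    paste0("sigma", if (kc %in% names(tied)) tied[[kc]] else k)
  }, character(1))
  syms <- c("alpha", "beta1", "beta2", "beta3", "beta4",
            if (K) as.vector(rbind(paste0("a", 1:K), paste0("mu", 1:K), sig_name)),
            if (J) paste0("iv", 1:J))
  res <- vapply(syms, resolve, numeric(2))
  idx <- res[1, ]; val <- res[2, ]
  g <- function(th, j) if (is.na(idx[j])) val[j] else th[idx[j]]

  function(th) {
    eta <- g(th, 2) + g(th, 3) * t
    if (!m1) eta <- eta + g(th, 4) * t2 + g(th, 5) * t3
    p <- 5L
    for (k in seq_len(K)) {
      a <- g(th, p + 1L); mu <- g(th, p + 2L); sg <- g(th, p + 3L)
      eta <- eta + (a / t) * exp(-(lt - mu)^2 / (2 * sg * sg))
      p <- p + 3L
    }
    for (j in seq_len(J)) {
      eta <- eta + g(th, p + j) * Z[[j]]
    }
    if (m1) {
      al <- g(th, 1L)
      al + (1 - al) * stats::plogis(eta)
    } else {
      exp(eta)
    }
  }
}
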