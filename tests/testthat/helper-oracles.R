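# Independent brute-force oracles used to cross-check the package's
# estimators. These deliberately re-derive each quantity from first
# principles (explicit risk sets, quadrature over the lag CDF, grid search)
# rather than calling the code paths they validate.

# Product-limit estimate by direct risk-set enumeration.
km_oracle <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# Two-group log-rank chi-square from an explicit (O - E)^2 / V risk-set table.
logrank_oracle <- function(time, event, group) {
  tt <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in tt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Breslow partial log-likelihood for one covariate, summed event by event.
cox_partial_loglik <- function(beta, time, event, x) {
  vapply(beta, function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }, numeric(1))
}

# Deterministic lag-phase growth factor E[N(t)]/n from the lag CDF:
# (1 - v) + v * [ (1 - F(t)) + integral_0^t exp(mu (t - s)) dF(s) ].
lag_factor_oracle <- function(spec, mu, t_grid) {
  v <- spec$viable_frac
  vapply(t_grid, function(tt) {
    contrib <- if (spec$kind == "empirical") {
      mean(ifelse(spec$sample <= tt, exp(mu * (tt - spec$sample)), 1))
    } else {
      if (spec$kind == "normal") {
        z0 <- stats::pnorm(0, spec$mean_h, spec$sd_h)
        dens <- function(s) stats::dnorm(s, spec$mean_h, spec$sd_h) / (1 - z0)
        cdf <- function(s) {
          (stats::pnorm(s, spec$mean_h, spec$sd_h) - z0) / (1 - z0)
        }
      } else {
        dens <- function(s) stats::dunif(s, spec$lo_h, spec$hi_h)
        cdf <- function(s) stats::punif(s, spec$lo_h, spec$hi_h)
      }
      grown <- if (tt <= 0) 0 else {
        stats::integrate(function(s) exp(mu * (tt - s)) * dens(s),
                         0, tt, rel.tol = 1e-10, abs.tol = 1e-12)$value
      }
      (1 - cdf(tt)) + grown
    }
    (1 - v) + v * contrib
  }, numeric(1))
}

# Endpoint estimator of two-state switching rates as a pure function of the
# four observed fractions, for delta-method error propagation.
switch_endpoint_estimator <- function(f0_on, fg_on, f0_off, fg_off, g) {
  ratio <- (fg_on - fg_off) / (f0_on - f0_off)
  lambda <- ratio^(1 / g)
  lg <- lambda^g
  f_inf <- (fg_on - f0_on * lg) / (1 - lg)
  s <- 1 - lambda
  c(a = s - f_inf * s, b = f_inf * s)
}

# Delta-method SEs of the endpoint switching-rate estimates under binomial
# sampling of n cells propagated at each generation. The endpoint variance
# follows the recursion Var(f_k) = lambda^2 Var(f_{k-1}) + f_k(1-f_k)/n;
# the estimator jacobian w.r.t. the two (independent) endpoint fractions is
# taken numerically.
switch_rate_se <- function(a, b, f0_on, f0_off, g, n) {
  lambda <- 1 - a - b
  end_var <- function(f0) {
    f <- f0
    v <- 0
    for (k in seq_len(g)) {
      f <- f * (1 - a) + (1 - f) * b
      v <- v * lambda^2 + f * (1 - f) / n
    }
    list(var = v, mean = f)
  }
  von <- end_var(f0_on)
  voff <- end_var(f0_off)
  eps <- 1e-7
  base <- switch_endpoint_estimator(f0_on, von$mean, f0_off, voff$mean, g)
  J_on <- (switch_endpoint_estimator(f0_on, von$mean + eps, f0_off,
                                     voff$mean, g) - base) / eps
  J_off <- (switch_endpoint_estimator(f0_on, von$mean, f0_off,
                                      voff$mean + eps, g) - base) / eps
  c(se_a = unname(sqrt(J_on[["a"]]^2 * von$var + J_off[["a"]]^2 * voff$var)),
    se_b = unname(sqrt(J_on[["b"]]^2 * von$var + J_off[["b"]]^2 * voff$var)))
}
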