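# ON/OFF expression-state dynamics: per-generation two-state switching rates
# estimated from hysteresis experiments, the dilution null model, and protein
# production per generation.
#
# The population ON fraction follows the two-state Markov recursion
#   f_{t+1} = f_t (1 - a) + (1 - f_t) b,
# with a = P(ON -> OFF) and b = P(OFF -> ON) per generation. Its closed form
# is f_g = f_inf + (f_0 - f_inf) lambda^g with f_inf = b/(a + b) and
# lambda = 1 - a - b. Two cultures started from opposite expression histories
# (ON-pregrown vs OFF-pregrown) give two equations that identify (a, b).

#' Construct an ON-fraction series
#'
#' @param initial_condition Label, e.g. `"ON-pregrown"` or `"OFF-pregrown"`.
#' @param generations Increasing non-negative vector of generation counts.
#' @param frac_on Matching vector of ON fractions in `[0, 1]`.
#' @return An object of class `on_fraction_series`.
#' @export
on_fraction_series <- function(initial_condition, generations, frac_on) {
  if (length(generations) != length(frac_on) || length(generations) < 2) {
    stop("a series needs at least 2 (generations, frac_on) points")
  }
  if (any(diff(generations) <= 0) || any(generations < 0)) {
    stop("`generations` must be non-negative and increasing")
  }
  if (any(frac_on < 0) || any(frac_on > 1)) {
    stop("`frac_on` must lie in [0, 1]")
  }
  structure(list(initial_condition = as.character(initial_condition),
                 generations = as.numeric(generations),
                 frac_on = as.numeric(frac_on)),
            class = "on_fraction_series")
}

#' Pure-dilution null expectation for a fluorescent signal
#'
#' Expected signal after `g` generations when a culture stops producing the
#' protein entirely and the existing pool is only diluted by cell division:
#' `f0 * 2^(-g)`.
#'
#' @param f0 Initial signal (arbitrary units, non-negative).
#' @param g Generations elapsed (non-negative, vectorized).
#' @return Expected diluted signal.
#' @export
dilution_null <- function(f0, g) {
  stopifnot(all(f0 >= 0), all(g >= 0))
  f0 * 2^(-g)
}

#' Protein production per generation above the dilution null
#'
#' Over the final two points of a fluorescence series (F1 at g1, F2 at g2),
#' the observed signal minus the dilution-expected remnant of F1, per
#' generation: `(F2 - F1 * 2^(-(g2 - g1))) / (g2 - g1)`. Zero means the
#' signal evolves exactly as passive dilution predicts.
#'
#' @param series Data frame (or list) with `generations` and `mean_signal`,
#'   at least two points, generations increasing.
#' @return Production in signal units per generation.
#' @export
production_rate <- function(series) {
  g <- series$generations
  f <- series$mean_signal
  if (is.null(g) || is.null(f) || length(g) < 2) {
    stop("series needs `generations` and `mean_signal` with at least 2 points")
  }
  n <- length(g)
  dg <- g[n] - g[n - 1]
  if (dg == 0) stop("final two points share the same generation count")
  (f[n] - f[n - 1] * 2^(-dg)) / dg
}

# Closed-form ON-fraction trajectory of the two-state chain.
.switch_trajectory <- function(a, b, f0, g) {
  s <- a + b
  if (s == 0) return(rep(f0, length(g)))
  f_inf <- b / s
  f_inf + (f0 - f_inf) * (1 - s)^g
}

#' Fitted ON-fraction trajectory
#'
#' Evaluates the closed-form two-state chain `f_g = f_inf + (f0 - f_inf) *
#' lambda^g` for fitted switching rates.
#'
#' @param rates A `switch_rates` object from [estimate_switch_rates()].
#' @param f0 Initial ON fraction.
#' @param g Vector of generation counts.
#' @return ON fractions at `g`.
#' @export
switch_trajectory <- function(rates, f0, g) {
  stopifnot(inherits(rates, "switch_rates"))
  .switch_trajectory(rates$a, rates$b, f0, g)
}

#' Estimate per-generation ON/OFF switching rates from hysteresis series
#'
#' Given paired ON-fraction series from an ON-pregrown and an OFF-pregrown
#' culture measured over the same number of generations, solves the
#' closed-form two-state chain for the per-generation switching rates:
#' the difference of the two trajectories decays as `lambda^g`, giving
#' `lambda` from the endpoint difference ratio, after which the shared
#' stationary fraction gives `b/(a+b)`.
#'
#' The default `"endpoints"` method uses only the first and last point of
#' each series (two equations, two unknowns). The `"least_squares"` method
#' fits the closed form to all points of both series by bounded
#' minimization of squared residuals.
#'
#' @param on_series,off_series [on_fraction_series()] objects from the two
#'   initial conditions, spanning the same generation count.
#' @param method `"endpoints"` (default) or `"least_squares"`.
#' @return Object of class `switch_rates`: `a` (ON->OFF), `b` (OFF->ON),
#'   `lambda` (= 1 - a - b), `f_inf` (= b/(a+b), NA when a = b = 0),
#'   `residual` (sum of squared residuals of the fitted closed form over
#'   all supplied points) and `clipped` (TRUE when the raw solution fell
#'   outside `[0, 1]^2` and was clipped).
#' @export
estimate_switch_rates <- function(on_series, off_series,
                                  method = c("endpoints", "least_squares")) {
  stopifnot(inherits(on_series, "on_fraction_series"),
            inherits(off_series, "on_fraction_series"))
  method <- match.arg(method)

  g_on <- on_series$generations - on_series$generations[1]
  g_off <- off_series$generations - off_series$generations[1]
  g_end <- g_on[length(g_on)]
  if (abs(g_end - g_off[length(g_off)]) > 1e-8) {
    stop("the two series must span the same number of generations")
  }
  if (g_end <= 0) stop("series span zero generations")
  f0_on <- on_series$frac_on[1]
  f0_off <- off_series$frac_on[1]
  fg_on <- on_series$frac_on[length(g_on)]
  fg_off <- off_series$frac_on[length(g_off)]

  if (method == "endpoints") {
    d0 <- f0_on - f0_off
    dg <- fg_on - fg_off
    if (abs(d0) < 1e-12) {
      stop("initial ON fractions coincide; the two series carry no contrast")
    }
    ratio <- dg / d0
    if (abs(ratio - 1) < 1e-12) {
      a <- 0; b <- 0
    } else if (ratio <= 0 || ratio > 1) {
      stop(sprintf(
        "no admissible eigenvalue: endpoint difference ratio %.4g outside (0, 1]",
        ratio))
    } else {
      lambda <- ratio^(1 / g_end)
      lg <- lambda^g_end
      f_inf <- (fg_on - f0_on * lg) / (1 - lg)
      s <- 1 - lambda
      b <- f_inf * s
      a <- s - b
    }
    clipped <- a < 0 || a > 1 || b < 0 || b > 1
    if (clipped) {
      warning("switching rates clipped to [0, 1]")
      a <- min(max(a, 0), 1)
      b <- min(max(b, 0), 1)
    }
  } else {
    sse <- function(par) {
      pred_on <- .switch_trajectory(par[1], par[2], f0_on, g_on)
      pred_off <- .switch_trajectory(par[1], par[2], f0_off, g_off)
      sum((pred_on - on_series$frac_on)^2) +
        sum((pred_off - off_series$frac_on)^2)
    }
    start <- tryCatch({
      e <- estimate_switch_rates(on_series, off_series, "endpoints")
      c(e$a, e$b)
    }, error = function(e) c(0.1, 0.1))
    opt <- stats::optim(pmin(pmax(start, 1e-6), 1 - 1e-6), sse,
                        method = "L-BFGS-B", lower = 0, upper = 1)
    a <- opt$par[1]; b <- opt$par[2]
    clipped <- FALSE
  }

  res <- sum((.switch_trajectory(a, b, f0_on, g_on) - on_series$frac_on)^2) +
    sum((.switch_trajectory(a, b, f0_off, g_off) - off_series$frac_on)^2)
  structure(list(a = a, b = b, lambda = 1 - a - b,
                 f_inf = if (a + b > 0) b / (a + b) else NA_real_,
                 residual = res, clipped = clipped),
            class = "switch_rates")
}

#' @export
print.switch_rates <- function(x, ...) {
  cat(sprintf(
    "<switch_rates> a (ON->OFF) = %.4g, b (OFF->ON) = %.4g per generation\n  lambda = %.4g, stationary ON fraction = %.4g, SSE = %.3g\n",
    x$a, x$b, x$lambda, x$f_inf, x$residual))
  invisible(x)
}
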