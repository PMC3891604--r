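# Population-level fitness metrics from plate-reader OD600 time series.
#
# The central quantities are MaxR (maximal specific growth rate on glucose,
# the regression slope of ln OD in an early OD band) and GMR (geometric-mean
# growth rate, ln(od_hi/od_lo) divided by the time the culture spends between
# the two interpolated OD bounds). Their ratio GMR/MaxR measures how
# efficiently a strain transits the diauxic shift.

#' Construct a growth curve
#'
#' One well's OD600 readings against time, with strain/condition labels.
#' All population-level metrics in the package start from this object.
#'
#' @param time_h Numeric vector of sampling times in hours, strictly
#'   increasing (plate readers typically sample every 15 min).
#' @param od600 Numeric vector of positive OD600 readings, same length as
#'   `time_h`; at least 10 samples.
#' @param well_id,strain,condition Labels carried through to summaries.
#'   Conventional conditions are `"HG"` (stable high glucose), `"LG"`,
#'   `"LG+Mal"` and `"LG+Gal"` (diauxic media), but any label is accepted.
#' @return An object of class `growth_curve`.
#' @examples
#' t <- seq(0, 12, by = 0.25)
#' gc <- growth_curve(t, 0.05 * exp(0.4 * t), well_id = "A1", strain = "S288c")
#' max_rate(gc)
#' @export
growth_curve <- function(time_h, od600, well_id = "well", strain = NA_character_,
                         condition = NA_character_) {
  time_h <- as.numeric(time_h)
  od600 <- as.numeric(od600)
  if (length(time_h) != length(od600)) {
    stop("`time_h` and `od600` must have the same length")
  }
  if (length(time_h) < 10) {
    stop("a growth curve needs at least 10 samples")
  }
  if (anyNA(time_h) || anyNA(od600)) {
    stop("growth curve contains missing values")
  }
  if (any(diff(time_h) <= 0)) {
    stop("`time_h` must be strictly increasing")
  }
  if (any(od600 <= 0)) {
    stop("`od600` must be positive everywhere")
  }
  structure(
    list(well_id = as.character(well_id), strain = as.character(strain),
         condition = as.character(condition), time_h = time_h, od600 = od600),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> well %s (strain %s, condition %s): %d samples, %.2f-%.2f h, OD %.3f-%.3f\n",
              x$well_id, x$strain, x$condition, length(x$time_h),
              min(x$time_h), max(x$time_h), min(x$od600), max(x$od600)))
  invisible(x)
}

#' Smooth a growth curve and compute its specific growth rate
#'
#' Fits a cubic smoothing spline to OD vs time, then takes the derivative of
#' the log-transformed smoothed curve: mu(t) = d/dt ln OD_smooth(t) =
#' OD'(t)/OD(t). The default smoothing parameter `spar = 0.35` matches the
#' value commonly used for 15-min Bioscreen sampling.
#'
#' @param curve A [growth_curve()].
#' @param spar Smoothing parameter of [stats::smooth.spline()], in (0, 1].
#' @return An object of class `rate_profile`: a list with `time_h`,
#'   `od_smooth` and `mu` (specific growth rate, per hour) on the curve's
#'   own time grid.
#' @export
smooth_and_differentiate <- function(curve, spar = 0.35) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!is.numeric(spar) || length(spar) != 1 || spar <= 0 || spar > 1) {
    stop("`spar` must be a single number in (0, 1]")
  }
  fit <- stats::smooth.spline(curve$time_h, curve$od600, spar = spar)
  od_s <- stats::predict(fit, curve$time_h)$y
  if (any(od_s <= 0)) {
    # heavy smoothing of a noisy low-OD tail can undershoot zero; the rate is
    # undefined there, so floor at a fraction of the smallest observed OD
    floor_od <- min(curve$od600) * 1e-3
    warning("smoothed OD dipped below zero; flooring at ", signif(floor_od, 3))
    od_s <- pmax(od_s, floor_od)
  }
  dod <- stats::predict(fit, curve$time_h, deriv = 1)$y
  structure(
    list(well_id = curve$well_id, strain = curve$strain,
         condition = curve$condition, time_h = curve$time_h,
         od_smooth = od_s, mu = dod / od_s),
    class = "rate_profile"
  )
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("<rate_profile> well %s: %d samples, mu %.3f-%.3f /h\n",
              x$well_id, length(x$time_h), min(x$mu), max(x$mu)))
  invisible(x)
}

#' @export
as.data.frame.rate_profile <- function(x, ...) {
  data.frame(well_id = x$well_id, strain = x$strain, condition = x$condition,
             time_h = x$time_h, od_smooth = x$od_smooth, mu = x$mu,
             stringsAsFactors = FALSE)
}

#' Maximal specific growth rate (MaxR)
#'
#' Ordinary least-squares slope of ln(OD) versus time over all samples whose
#' OD lies in the early band (default 0.15-0.30), where cells still grow on
#' the preferred carbon source.
#'
#' @inheritParams smooth_and_differentiate
#' @param od_lo,od_hi OD bounds of the regression band.
#' @return MaxR in per hour.
#' @export
max_rate <- function(curve, od_lo = 0.15, od_hi = 0.30) {
  stopifnot(inherits(curve, "growth_curve"), od_lo > 0, od_hi > od_lo)
  sel <- curve$od600 >= od_lo & curve$od600 <= od_hi
  if (sum(sel) < 3) {
    stop(sprintf("fewer than 3 samples with OD in [%g, %g]; cannot fit MaxR",
                 od_lo, od_hi))
  }
  unname(stats::coef(stats::lm(log(curve$od600[sel]) ~ curve$time_h[sel]))[2])
}

# First upward crossing time of `level` by OD, found by monotone
# piecewise-cubic interpolation on a bracketing window around the crossing.
# Non-monotone OD (evaporation/settling artifacts) triggers a warning and the
# first upward crossing is used.
.crossing_time <- function(time_h, od, level, window = 3L) {
  n <- length(od)
  up <- which(od[-n] < level & od[-1] >= level)
  if (length(up) == 0) {
    stop(sprintf("curve never crosses OD %g from below", level))
  }
  if (length(up) > 1) {
    warning(sprintf("OD crosses %g upward %d times; using the first crossing",
                    level, length(up)))
  }
  i <- up[1]
  j0 <- max(1L, i - window)
  j1 <- min(n, i + 1L + window)
  f <- stats::splinefun(time_h[j0:j1], od[j0:j1], method = "monoH.FC")
  stats::uniroot(function(t) f(t) - level,
                 lower = time_h[i], upper = time_h[i + 1],
                 tol = .Machine$double.eps^0.75)$root
}

#' Interpolated OD crossing times
#'
#' Times at which the curve first crosses the lower and upper OD bounds from
#' below, by monotone spline interpolation around each crossing.
#'
#' @inheritParams max_rate
#' @return Named numeric vector `c(t_lo =, t_hi =)` in hours.
#' @export
crossing_times <- function(curve, od_lo = 0.15, od_hi = 0.75) {
  stopifnot(inherits(curve, "growth_curve"), od_lo > 0, od_hi > od_lo)
  c(t_lo = .crossing_time(curve$time_h, curve$od600, od_lo),
    t_hi = .crossing_time(curve$time_h, curve$od600, od_hi))
}

#' Geometric-mean growth rate (GMR)
#'
#' Average specific growth rate across a fixed OD interval spanning the
#' carbon transition: `ln(od_hi/od_lo) / (t_hi - t_lo)`, where the crossing
#' times are interpolated from the curve. With the default bounds this is
#' `ln(0.75/0.15)/t`, t being the transit time between OD 0.15 and 0.75.
#'
#' @inheritParams max_rate
#' @param od_lo,od_hi OD bounds of the transit interval.
#' @return GMR in per hour.
#' @export
gmr <- function(curve, od_lo = 0.15, od_hi = 0.75) {
  tc <- crossing_times(curve, od_lo, od_hi)
  log(od_hi / od_lo) / unname(tc["t_hi"] - tc["t_lo"])
}

#' Locate the lag-phase trough
#'
#' Finds the minimum specific growth rate over the analysis OD band and the
#' OD at which it occurs. A growth-rate minimum sitting at the top of the
#' band (OD = `od_hi`) means the rate never re-accelerated inside the band:
#' the curve has no detectable lag phase, and `od_at_min` is reported as
#' `od_hi` with `no_lag = TRUE`. A curve whose in-band rate variation is
#' below `trough_tol` (relative to the band maximum) is likewise flagged as
#' lag-free: its "minimum" is smoothing jitter, not a trough.
#'
#' @param profile A `rate_profile` from [smooth_and_differentiate()].
#' @param od_lo,od_hi OD bounds of the analysis band.
#' @param trough_tol Minimum relative rate drop (between the rate at the top
#'   of the band and the in-band minimum) required to call a trough.
#' @return List with `min_rate` (per hour), `od_at_min` and `no_lag`.
#' @export
lag_locus <- function(profile, od_lo = 0.15, od_hi = 0.75, trough_tol = 0.02) {
  stopifnot(inherits(profile, "rate_profile"))
  sel <- profile$od_smooth >= od_lo & profile$od_smooth <= od_hi
  if (sum(sel) < 2) {
    stop(sprintf("rate profile does not span the OD band [%g, %g]", od_lo, od_hi))
  }
  od_band <- profile$od_smooth[sel]
  mu_band <- profile$mu[sel]
  k <- which.min(mu_band)
  min_rate <- mu_band[k]
  top <- which.max(od_band)
  rel_drop <- (mu_band[top] - min_rate) / max(abs(mu_band))
  no_lag <- (k == top) || (rel_drop < trough_tol)
  list(min_rate = min_rate,
       od_at_min = if (no_lag) od_hi else od_band[k],
       no_lag = no_lag)
}

#' Mean growth rate over a window around the lag trough
#'
#' Average specific growth rate over the OD interval spanning
#' `doublings_before` doublings before and `doublings_after` doublings after
#' the lag-phase minimum, clipped to the analysis band. The degenerate
#' zero-width window returns the rate interpolated at `od_at_min` itself.
#'
#' @inheritParams lag_locus
#' @param od_at_min OD at the lag-phase minimum, from [lag_locus()].
#' @param doublings_before,doublings_after Window half-widths in doublings.
#' @return Mean rate in per hour.
#' @export
windowed_mean_rate <- function(profile, od_at_min, doublings_before = 1,
                               doublings_after = 0.1,
                               od_lo = 0.15, od_hi = 0.75) {
  stopifnot(inherits(profile, "rate_profile"),
            doublings_before >= 0, doublings_after >= 0)
  if (doublings_before == 0 && doublings_after == 0) {
    return(stats::approx(profile$od_smooth, profile$mu, xout = od_at_min,
                         ties = mean)$y)
  }
  w_lo <- max(od_lo, od_at_min * 2^(-doublings_before))
  w_hi <- min(od_hi, od_at_min * 2^(doublings_after))
  sel <- profile$od_smooth >= w_lo & profile$od_smooth <= w_hi
  if (sum(sel) < 2) {
    stop(sprintf("window [%g, %g] OD contains fewer than 2 samples", w_lo, w_hi))
  }
  mean(profile$mu[sel])
}

#' Summarize a growth curve
#'
#' Computes the full set of population-level metrics for one well: MaxR,
#' GMR, their ratio, the interpolated bound-crossing times, and the
#' lag-trough location, plus the mean rate over a window around the trough
#' when one exists.
#'
#' @inheritParams smooth_and_differentiate
#' @param od_lo,od_hi OD bounds of the GMR interval and the analysis band.
#' @param maxr_lo,maxr_hi OD bounds of the MaxR regression band.
#' @param window `c(doublings_before, doublings_after)` for the windowed
#'   mean rate around the trough, or `NULL` to skip.
#' @return An object of class `growth_summary` (also a one-row list):
#'   `max_rate`, `gmr`, `gmr_norm` (= gmr/max_rate), `t_lo`, `t_hi`,
#'   `min_rate`, `od_at_min`, `no_lag`, `window_rate`.
#' @export
growth_summary <- function(curve, od_lo = 0.15, od_hi = 0.75,
                           maxr_lo = 0.15, maxr_hi = 0.30,
                           spar = 0.35, window = c(1, 0.1)) {
  mr <- max_rate(curve, maxr_lo, maxr_hi)
  tc <- crossing_times(curve, od_lo, od_hi)
  g <- log(od_hi / od_lo) / unname(tc["t_hi"] - tc["t_lo"])
  prof <- smooth_and_differentiate(curve, spar = spar)
  loc <- lag_locus(prof, od_lo, od_hi)
  wr <- NA_real_
  if (!is.null(window) && !loc$no_lag) {
    wr <- tryCatch(
      windowed_mean_rate(prof, loc$od_at_min, window[1], window[2], od_lo, od_hi),
      error = function(e) NA_real_
    )
  }
  structure(
    list(well_id = curve$well_id, strain = curve$strain,
         condition = curve$condition,
         max_rate = mr, gmr = g, gmr_norm = g / mr,
         t_lo = unname(tc["t_lo"]), t_hi = unname(tc["t_hi"]),
         min_rate = loc$min_rate, od_at_min = loc$od_at_min,
         no_lag = loc$no_lag, window_rate = wr),
    class = "growth_summary"
  )
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf(
    "<growth_summary> well %s (%s, %s)\n  MaxR %.4f /h  GMR %.4f /h  GMR/MaxR %.3f\n  band transit %.2f-%.2f h  min rate %.4f /h at OD %.3f%s\n",
    x$well_id, x$strain, x$condition, x$max_rate, x$gmr, x$gmr_norm,
    x$t_lo, x$t_hi, x$min_rate, x$od_at_min,
    if (x$no_lag) " (no lag)" else ""))
  invisible(x)
}

#' @export
as.data.frame.growth_summary <- function(x, ...) {
  data.frame(well_id = x$well_id, strain = x$strain, condition = x$condition,
             max_rate = x$max_rate, gmr = x$gmr, gmr_norm = x$gmr_norm,
             t_lo = x$t_lo, t_hi = x$t_hi, min_rate = x$min_rate,
             od_at_min = x$od_at_min, no_lag = x$no_lag,
             window_rate = x$window_rate, stringsAsFactors = FALSE)
}

# Extract one relative GMR (gmr_norm) per condition from a named input that
# may hold growth_summary objects or bare numbers.
.rel_gmr <- function(x) {
  if (inherits(x, "growth_summary")) x$gmr_norm else as.numeric(x)
}

#' Fitness-variability index
#'
#' Ratio of the MaxR-normalized GMR in stable high glucose to the geometric
#' mean of the normalized GMRs in the three variable-media conditions
#' (`LG`, `LG+Mal`, `LG+Gal`). Values above 1 indicate that fitness drops in
#' variable media; a perfect generalist scores 1.
#'
#' @param summaries Named list (or named numeric vector) keyed by condition,
#'   holding either [growth_summary()] objects or relative GMR values.
#'   All four of `HG`, `LG`, `LG+Mal`, `LG+Gal` must be present.
#' @return List with `per_condition_rel_gmr` (named numeric) and
#'   `fitness_variability`.
#' @export
fitness_variability <- function(summaries) {
  need <- c("HG", "LG", "LG+Mal", "LG+Gal")
  missing <- setdiff(need, names(summaries))
  if (length(missing)) {
    stop("missing condition(s): ", paste(missing, collapse = ", "))
  }
  rel <- vapply(summaries[need], .rel_gmr, numeric(1))
  if (any(rel <= 0)) {
    stop("relative GMR must be positive in every condition (geometric mean undefined)")
  }
  fv <- rel[["HG"]] / exp(mean(log(rel[c("LG", "LG+Mal", "LG+Gal")])))
  list(per_condition_rel_gmr = rel, fitness_variability = unname(fv))
}

#' Resampling error of the fitness-variability index
#'
#' Repeats the fitness-variability calculation `n_resamples` times, each time
#' drawing one biological replicate per condition uniformly at random, and
#' returns the mean and standard deviation over resamples (the error bars of
#' the generalist-specialist index).
#'
#' @param replicates Named list keyed by condition (`HG`, `LG`, `LG+Mal`,
#'   `LG+Gal`); each element is a vector/list of relative GMR values or
#'   [growth_summary()] objects, one per biological replicate.
#' @param n_resamples Number of resamples (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `mean`, `sd` and the vector of resampled `values`.
#' @export
resample_variability <- function(replicates, n_resamples = 1000, seed = NULL) {
  need <- c("HG", "LG", "LG+Mal", "LG+Gal")
  missing <- setdiff(need, names(replicates))
  if (length(missing)) {
    stop("missing condition(s): ", paste(missing, collapse = ", "))
  }
  rel <- lapply(replicates[need], function(r) {
    if (inherits(r, "growth_summary")) r <- list(r)
    v <- vapply(if (is.list(r)) r else as.list(r), .rel_gmr, numeric(1))
    if (length(v) < 1) stop("each condition needs at least one replicate")
    v
  })
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(n_resamples), function(i) {
    draw <- vapply(rel, function(v) v[sample.int(length(v), 1)], numeric(1))
    names(draw) <- need
    fitness_variability(as.list(draw))$fitness_variability
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}
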