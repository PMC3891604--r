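# Synthetic-data generators for every input the pipeline consumes, each
# returning its ground truth alongside the data so estimators can be tested
# by recovery.
#
# Diauxic OD curves are generated from a specific-growth-rate-vs-OD function
# rather than a mechanistic substrate model: the population metrics (MaxR,
# GMR, trough location) are defined in rate-vs-OD space, so ground truth is
# exact there. The rate function is mu1 on glucose, a smooth half-cosine dip
# to a trough rate as glucose depletes, recovery to the adapted rate mu2 on
# the alternative carbon source, and a roll-off to stationary phase near the
# OD plateau.

#' Parameters of a synthetic biphasic (diauxic) growth curve
#'
#' @param od0 Initial OD.
#' @param mu1 Glucose-phase specific growth rate (per hour).
#' @param mu2 Post-shift adapted rate (per hour), `trough_rate <= mu2 <= mu1`.
#' @param od_shift OD at which deceleration begins.
#' @param trough_rate Rate at the bottom of the lag trough (per hour). Set
#'   `trough_rate = mu2 = mu1` for a trough-free exponential curve.
#' @param trough_width Width of the dip in doublings of OD; the trough
#'   bottom sits `trough_width/2` doublings above `od_shift`.
#' @param od_stationary OD plateau (carrying capacity of the well).
#' @param noise_sd Relative (lognormal) OD noise SD; 0 for noiseless curves.
#' @param sample_every_min Sampling interval in minutes (default 15, the
#'   usual plate-reader cadence).
#' @return An object of class `diauxic_params`.
#' @export
diauxic_params <- function(od0 = 0.05, mu1 = 0.45, mu2 = 0.2,
                           od_shift = 0.247, trough_rate = 0.05,
                           trough_width = 1, od_stationary = 1.5,
                           noise_sd = 0.01, sample_every_min = 15) {
  if (od0 <= 0 || od_shift <= od0 || od_stationary <= od_shift) {
    stop("need 0 < od0 < od_shift < od_stationary")
  }
  if (trough_rate <= 0 || trough_rate > mu2 || mu2 > mu1) {
    stop("need 0 < trough_rate <= mu2 <= mu1")
  }
  if (trough_width <= 0) stop("`trough_width` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(od0 = od0, mu1 = mu1, mu2 = mu2, od_shift = od_shift,
                 trough_rate = trough_rate, trough_width = trough_width,
                 od_stationary = od_stationary, noise_sd = noise_sd,
                 sample_every_min = sample_every_min),
            class = "diauxic_params")
}

# Specific growth rate as a function of OD for a diauxic parameter set,
# before the stationary roll-off.
.mu_base <- function(od, p) {
  x <- log2(od)
  xs <- log2(p$od_shift)
  hw <- p$trough_width / 2
  xc <- xs + hw
  xe <- xs + p$trough_width
  mu <- numeric(length(x))
  lo <- x <= xs
  dn <- x > xs & x <= xc
  up <- x > xc & x <= xe
  hi <- x > xe
  mu[lo] <- p$mu1
  mu[dn] <- p$mu1 - (p$mu1 - p$trough_rate) *
    (0.5 - 0.5 * cos(pi * (x[dn] - xs) / hw))
  mu[up] <- p$trough_rate + (p$mu2 - p$trough_rate) *
    (0.5 - 0.5 * cos(pi * (x[up] - xc) / hw))
  mu[hi] <- p$mu2
  mu
}

# Stationary-phase roll-off multiplier: 1 below 0.9 * plateau, half-cosine
# down to a small floor at the plateau.
.rolloff <- function(od, p, floor = 1e-3) {
  start <- 0.9 * p$od_stationary
  m <- rep(1, length(od))
  sel <- od > start
  frac <- pmin((od[sel] - start) / (p$od_stationary - start), 1)
  m[sel] <- floor + (1 - floor) * (0.5 + 0.5 * cos(pi * frac))
  m
}

#' True rate-vs-OD function of a synthetic diauxic curve
#'
#' @param od Vector of OD values.
#' @param params A [diauxic_params()].
#' @return Specific growth rate (per hour) at each OD.
#' @export
diauxic_rate_function <- function(od, params) {
  stopifnot(inherits(params, "diauxic_params"))
  .mu_base(od, params) * .rolloff(od, params)
}

#' Generate a synthetic diauxic growth curve with known ground truth
#'
#' Integrates the rate-vs-OD function on a fine grid (quadrature of
#' `dt = ln2 dx / mu(x)` in doublings `x = log2 OD`), samples the resulting
#' OD trajectory at the plate-reader cadence, and multiplies by lognormal
#' noise. Analytic ground truth (crossing times of the standard OD bounds,
#' true GMR, trough location) is attached as the `"truth"` attribute.
#'
#' @param params A [diauxic_params()].
#' @param seed Integer seed for the noise draw.
#' @param duration_h Total sampled duration in hours; `NULL` (default) runs
#'   until the curve is within 3% of the plateau, capped at 72 h.
#' @param well_id,strain,condition Labels passed to [growth_curve()].
#' @return A [growth_curve()] with attribute `truth`: a list holding
#'   `t_of_od` (function OD -> hours), `t_lo`, `t_hi` (crossing times of OD
#'   0.15/0.75), `gmr`, `max_rate`, `has_trough`, `od_trough`, `min_rate`
#'   and the generating `params`.
#' @export
gen_diauxic_curve <- function(params, seed = 1L, duration_h = NULL,
                              well_id = "synthetic", strain = "synthetic",
                              condition = NA_character_) {
  stopifnot(inherits(params, "diauxic_params"))
  p <- params
  x0 <- log2(p$od0)
  x_end <- log2(0.995 * p$od_stationary)
  xs <- seq(x0, x_end, length.out = 6000L)
  mu <- .mu_base(2^xs, p) * .rolloff(2^xs, p)
  integrand <- log(2) / mu
  # cumulative trapezoid: time to reach each grid OD
  dx <- diff(xs)
  t_x <- c(0, cumsum(dx * (integrand[-1] + integrand[-length(xs)]) / 2))
  x_of_t <- stats::splinefun(t_x, xs, method = "monoH.FC")
  t_of_x <- stats::splinefun(xs, t_x, method = "monoH.FC")
  t_of_od <- function(od) t_of_x(log2(od))

  if (is.null(duration_h)) {
    duration_h <- min(72, ceiling(t_of_od(0.97 * p$od_stationary)))
  }
  t_s <- seq(0, duration_h, by = p$sample_every_min / 60)
  od_clean <- ifelse(t_s <= max(t_x), 2^x_of_t(t_s), 2^x_end)
  od <- od_clean
  if (p$noise_sd > 0) {
    set.seed(seed)
    od <- od * exp(stats::rnorm(length(od), 0, p$noise_sd))
  }
  # estimator-consistent MaxR truth: the OLS slope the regression band would
  # yield on the noiseless sampled curve
  mb <- od_clean >= 0.15 & od_clean <= 0.30
  true_maxr <- if (sum(mb) >= 3) {
    unname(stats::coef(stats::lm(log(od_clean[mb]) ~ t_s[mb]))[2])
  } else {
    p$mu1
  }

  has_trough <- p$trough_rate < p$mu1
  od_trough <- if (has_trough) p$od_shift * 2^(p$trough_width / 2) else NA_real_
  t_lo <- t_of_od(0.15)
  t_hi <- t_of_od(0.75)
  truth <- list(
    t_of_od = t_of_od,
    mu_of_od = function(od) diauxic_rate_function(od, p),
    t_lo = t_lo, t_hi = t_hi,
    gmr = log(0.75 / 0.15) / (t_hi - t_lo),
    max_rate = true_maxr,
    has_trough = has_trough, od_trough = od_trough,
    min_rate = if (has_trough) {
      diauxic_rate_function(od_trough, p)
    } else {
      min(diauxic_rate_function(c(0.15, 0.75), p))
    },
    params = p
  )
  curve <- growth_curve(t_s, od, well_id = well_id, strain = strain,
                        condition = condition)
  attr(curve, "truth") <- truth
  curve
}

#' Generate a censored single-cell lag table with known ground truth
#'
#' Draws per-cell lag times from a [lag_spec()]; lags beyond the horizon and
#' non-viable cells are emitted as censored at the horizon.
#'
#' @param spec A [lag_spec()].
#' @param n Number of cells.
#' @param horizon_h Observation horizon in hours (default 20).
#' @param seed Integer seed.
#' @param strain Strain label.
#' @return A [lag_table()] with attribute `truth` holding the raw `tau` and
#'   `status` vectors.
#' @export
gen_lag_table <- function(spec, n, horizon_h = 20, seed = 1L,
                          strain = "synthetic") {
  stopifnot(inherits(spec, "lag_spec"), n >= 1)
  set.seed(seed)
  d <- draw_lags(spec, n)
  event <- as.integer(d$status == 1 & d$tau <= horizon_h)
  tbl <- lag_table(data.frame(
    cell_id = sprintf("cell%05d", seq_len(n)),
    strain = strain,
    lag_h = ifelse(event == 1, d$tau, horizon_h),
    event = event,
    stringsAsFactors = FALSE
  ))
  attr(tbl, "truth") <- d
  tbl
}

#' Generate a two-group lag table with a known hazard ratio
#'
#' Exponential lag times with per-cell hazard `base_rate * exp(beta * x)`
#' for a binary genotype covariate `x`, censored at the horizon — the
#' forward model of a Cox fit, for parameter-recovery tests.
#'
#' @param n Number of cells.
#' @param beta True log hazard ratio of the genotype.
#' @param base_rate Baseline budding hazard (per hour).
#' @param p_exposed Fraction of cells with genotype 1.
#' @param horizon_h Censoring horizon in hours.
#' @param seed Integer seed.
#' @param covariate Name of the covariate column.
#' @return A [lag_table()] with the covariate column attached.
#' @export
gen_cox_lag_table <- function(n, beta, base_rate = 0.15, p_exposed = 0.5,
                              horizon_h = 20, seed = 1L,
                              covariate = "genotype") {
  set.seed(seed)
  x <- stats::rbinom(n, 1, p_exposed)
  tau <- stats::rexp(n, rate = base_rate * exp(beta * x))
  event <- as.integer(tau <= horizon_h)
  df <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                   strain = "synthetic",
                   lag_h = pmin(tau, horizon_h),
                   event = event,
                   stringsAsFactors = FALSE)
  df[[covariate]] <- x
  lag_table(df)
}

#' Generate competition count data from the simulator
#'
#' Runs [simulate_schedule()] for two strains, samples `n_events` label
#' counts multinomially from the true proportions at each observation time,
#' applies forward misclassification, and attaches the true total population
#' sizes as plating densities.
#'
#' @param strains List of two [strain_params()].
#' @param schedule An [env_schedule()].
#' @param init_props Initial proportions.
#' @param rates An [error_rates()] applied forward to the sampled labels.
#' @param n_events Cytometry events per time point (e.g. 50,000); `Inf`
#'   switches off sampling noise (counts exactly proportional to the true
#'   proportions, scaled to 1e6 events, with deterministic misclassification).
#' @param obs_times_h Observation times in hours (snapped to the grid).
#' @param config A [sim_config()].
#' @param seed Integer seed for the count sampling.
#' @return A [count_table()] with attribute `truth`: the `sim_result` and
#'   the true proportions at the observation times.
#' @export
gen_competition_counts <- function(strains, schedule, init_props,
                                   rates = error_rates(),
                                   n_events = 50000, obs_times_h,
                                   config = sim_config(), seed = 1L) {
  sim <- simulate_schedule(strains, schedule, init_props, config)
  idx <- vapply(obs_times_h, function(t) which.min(abs(sim$time_h - t)),
                integer(1))
  p_true <- sim$p[idx, 1]
  N_true <- rowSums(sim$N)[idx]
  set.seed(seed)
  if (is.infinite(n_events)) {
    q_true <- p_true * 1e6
    r_true <- (1 - p_true) * 1e6
    q_obs <- (1 - rates$e_rq) * q_true + rates$e_qr * r_true
    r_obs <- rates$e_rq * q_true + (1 - rates$e_qr) * r_true
  } else {
    q_true <- stats::rbinom(length(p_true), n_events, p_true)
    r_true <- n_events - q_true
    q_keep <- stats::rbinom(length(q_true), q_true, 1 - rates$e_rq)
    r_flip <- stats::rbinom(length(r_true), r_true, rates$e_qr)
    q_obs <- q_keep + r_flip
    r_obs <- (q_true - q_keep) + (r_true - r_flip)
  }
  tbl <- count_table(data.frame(time_h = sim$time_h[idx],
                                count_query = q_obs,
                                count_reference = r_obs,
                                total_density = N_true))
  attr(tbl, "truth") <- list(sim = sim, p_query = p_true)
  tbl
}

#' Generate paired hysteresis ON-fraction series
#'
#' Iterates the two-state per-generation switching chain from an ON-pregrown
#' and an OFF-pregrown initial condition, with binomial sampling of
#' `n_cells` cells propagated at each generation (`Inf` for the exact
#' deterministic recursion). Generation 0 reports the exact inoculum
#' fraction.
#'
#' @param a,b Per-generation switching probabilities (ON->OFF, OFF->ON).
#' @param f0_on,f0_off Initial ON fractions of the two cultures.
#' @param generations Integer number of generations to iterate.
#' @param n_cells Cells sampled per generation (`Inf` = noiseless).
#' @param seed Integer seed.
#' @return List with `on` and `off` ([on_fraction_series()] objects) and
#'   attribute `truth` = list(a, b).
#' @export
gen_on_fraction <- function(a, b, f0_on = 0.95, f0_off = 0.05,
                            generations = 10L, n_cells = 10000, seed = 1L) {
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1, generations >= 1)
  set.seed(seed)
  run <- function(f0) {
    f <- numeric(generations + 1)
    f[1] <- f0
    for (g in seq_len(generations)) {
      nxt <- f[g] * (1 - a) + (1 - f[g]) * b
      f[g + 1] <- if (is.infinite(n_cells)) nxt else {
        stats::rbinom(1, n_cells, nxt) / n_cells
      }
    }
    f
  }
  out <- list(
    on = on_fraction_series("ON-pregrown", 0:generations, run(f0_on)),
    off = on_fraction_series("OFF-pregrown", 0:generations, run(f0_off))
  )
  attr(out, "truth") <- list(a = a, b = b)
  out
}

#' Generate a synthetic strain panel spanning the lag-phenotype space
#'
#' Ships `n_strains` archetypes spanning short-lag/low-MaxR generalists to
#' long-lag/high-MaxR glucose specialists, with an imposed positive
#' mean-lag/SD-lag relationship and a viable fraction that declines with
#' mean lag — the phenotype space observed across feral yeast strains. Each
#' strain carries diauxic-curve parameters for the four standard media: a
#' trough-free HG curve and LG / LG+Gal / LG+Mal curves whose trough depth
#' scales with the strain's lag phenotype (deepest in LG, shallowest in
#' LG+Mal).
#'
#' @param n_strains Number of strains (default 18).
#' @param seed Integer seed for the phenotype jitter.
#' @return List of strains; each has `name`, `mean_lag_h`, `lag`
#'   (a [lag_spec()]) and `curves`, a named list of [diauxic_params()] keyed
#'   by condition (`HG`, `LG`, `LG+Gal`, `LG+Mal`).
#' @export
gen_strain_panel <- function(n_strains = 18L, seed = 42L) {
  set.seed(seed)
  mean_lag <- seq(2, 16, length.out = n_strains) *
    exp(stats::rnorm(n_strains, 0, 0.08))
  sd_lag <- 0.3 * mean_lag * exp(stats::rnorm(n_strains, 0, 0.1))
  viable <- 1 - 0.25 * (mean_lag - min(mean_lag)) / diff(range(mean_lag))
  sev <- (mean_lag - 1) / 16  # lag severity in (0, 1): scales trough depth
  mu1 <- 0.35 + 0.15 * sev    # specialist tradeoff: longer lag, higher MaxR
  lapply(seq_len(n_strains), function(i) {
    trough_for <- function(depth) {
      # depth in (0,1]: fraction of mu2 remaining at the trough bottom
      diauxic_params(mu1 = mu1[i], mu2 = 0.6 * mu1[i],
                     trough_rate = max(0.015, 0.6 * mu1[i] * depth),
                     trough_width = 0.8 + 1.2 * sev[i], noise_sd = 0.01)
    }
    hg <- diauxic_params(mu1 = mu1[i], mu2 = mu1[i], trough_rate = mu1[i],
                         trough_width = 1, noise_sd = 0.01)
    list(
      name = sprintf("SYN%02d", i),
      mean_lag_h = mean_lag[i],
      lag = lag_spec("normal", mean_h = mean_lag[i], sd_h = sd_lag[i],
                     viable_frac = viable[i]),
      curves = list(
        "HG" = hg,
        "LG" = trough_for(1 - 0.9 * sev[i]),
        "LG+Gal" = trough_for(1 - 0.7 * sev[i]),
        "LG+Mal" = trough_for(1 - 0.5 * sev[i])
      )
    )
  })
}
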