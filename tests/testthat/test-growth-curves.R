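# Population-level growth metrics: MaxR, GMR, lag trough, fitness variability.

exp_curve <- function(rate, od0 = 0.05, t_max = 8, by = 0.25, ...) {
  t <- seq(0, t_max, by = by)
  growth_curve(t, od0 * exp(rate * t), ...)
}

test_that("growth_curve rejects invalid inputs", {
  t <- seq(0, 5, by = 0.25)
  expect_error(growth_curve(rev(t), 0.05 * exp(0.3 * t)), "increasing")
  expect_error(growth_curve(t, -0.05 * exp(0.3 * t)), "positive")
  expect_error(growth_curve(t[1:5], rep(0.3, 5)), "at least 10")
  expect_error(growth_curve(t, rep(0.3, 5)), "same length")
})

test_that("rate profile recovers constant and exponential specific growth rates", {
  const <- growth_curve(seq(0, 5, by = 0.25), rep(0.3, 21))
  expect_lt(max(abs(smooth_and_differentiate(const)$mu)), 1e-8)

  prof <- smooth_and_differentiate(exp_curve(0.4))
  band <- prof$od_smooth >= 0.15 & prof$od_smooth <= 0.75
  expect_lt(max(abs(prof$mu[band] - 0.4)), 1e-2)

  expect_error(smooth_and_differentiate(exp_curve(0.4), spar = 0), "spar")
})

test_that("rate profile resolves the deceleration-trough-reacceleration shape", {
  p <- diauxic_params(mu1 = 0.45, mu2 = 0.2, trough_rate = 0.05,
                      od_shift = 0.247, trough_width = 1, noise_sd = 0.005)
  cur <- gen_diauxic_curve(p, seed = 5)
  truth <- attr(cur, "truth")
  prof <- smooth_and_differentiate(cur)
  band <- prof$od_smooth >= 0.15 & prof$od_smooth <= 0.75
  # recovered rate tracks the generator's analytic rate-vs-OD function
  err <- abs(prof$mu[band] - truth$mu_of_od(prof$od_smooth[band]))
  expect_lt(max(err), 0.05)
  # local minimum near the injected trough centre
  loc <- lag_locus(prof)
  expect_false(loc$no_lag)
  expect_lt(abs(loc$od_at_min - truth$od_trough), 0.05)
})

test_that("MaxR is the ln-OD regression slope over the early band", {
  expect_equal(max_rate(exp_curve(0.5)), 0.5, tolerance = 1e-9)
  # multiplicative 1% noise: estimates distributed as 0.5 +/- 0.02 (~2 SE)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    t <- seq(0, 8, by = 0.25)
    od <- 0.05 * exp(0.5 * t) * exp(rnorm(length(t), 0, 0.01))
    max_rate(growth_curve(t, od)) - 0.5
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.005)
  expect_lt(stats::sd(errs), 0.02)
  # curve never reaching the band
  low <- growth_curve(seq(0, 5, by = 0.25), rep(0.05, 21))
  expect_error(max_rate(low), "0.15")
})

test_that("GMR matches its definition on curves with known crossing times", {
  # exact exponential: GMR equals the rate for any bounds
  for (r in c(0.12, 0.3, 0.55)) {
    expect_equal(gmr(exp_curve(r, t_max = 26)), r, tolerance = 1e-4)
  }
  # accelerating curve constructed to cross 0.15 at t = 2 and 0.75 at t = 4
  a <- (log(5) - 0.4) / 2
  t <- seq(0, 6, by = 0.25)
  od <- 0.15 * exp(a * (t - 2) + 0.1 * (t - 2)^2)
  cur <- growth_curve(t, od)
  tc <- crossing_times(cur)
  expect_equal(unname(tc), c(2, 4), tolerance = 1e-4)
  expect_equal(gmr(cur), log(5) / 2, tolerance = 1e-3)
})

test_that("GMR agrees with the generator's analytic crossing times and is grid-invariant", {
  p15 <- diauxic_params(noise_sd = 0, sample_every_min = 15)
  p05 <- diauxic_params(noise_sd = 0, sample_every_min = 5)
  c15 <- gen_diauxic_curve(p15)
  c05 <- gen_diauxic_curve(p05)
  truth <- attr(c15, "truth")
  expect_lt(abs(gmr(c15) - truth$gmr), 1e-3)
  expect_lt(abs(gmr(c15) - gmr(c05)), 1e-3)
})

test_that("deeper lag troughs decrease GMR monotonically but leave MaxR unchanged", {
  # trough placed above the MaxR band so the early regression is untouched
  troughs <- c(0.20, 0.12, 0.06, 0.03)
  res <- lapply(troughs, function(tr) {
    p <- diauxic_params(mu1 = 0.45, mu2 = 0.2, od_shift = 0.32,
                        trough_rate = tr, noise_sd = 0)
    cur <- gen_diauxic_curve(p)
    c(gmr = gmr(cur), maxr = max_rate(cur))
  })
  gmrs <- vapply(res, `[[`, numeric(1), "gmr")
  maxrs <- vapply(res, `[[`, numeric(1), "maxr")
  expect_true(all(diff(gmrs) < 0))
  expect_lt(diff(range(maxrs)), 1e-9)
})

test_that("lag locus flags curves without a trough", {
  # monotone decelerating curve: dip bottom beyond the band, so the rate is
  # still falling at OD 0.75 (no re-acceleration inside the band)
  p <- diauxic_params(mu1 = 0.45, mu2 = 0.2, od_shift = 0.2,
                      trough_rate = 0.05, trough_width = 5,
                      od_stationary = 3, noise_sd = 0)
  prof <- smooth_and_differentiate(gen_diauxic_curve(p))
  loc <- lag_locus(prof)
  expect_true(loc$no_lag)
  expect_equal(loc$od_at_min, 0.75)

  # pure exponential: rate flat in band, no trough, min_rate = rate
  prof2 <- smooth_and_differentiate(exp_curve(0.4))
  loc2 <- lag_locus(prof2)
  expect_true(loc2$no_lag)
  expect_equal(loc2$od_at_min, 0.75)
  expect_equal(loc2$min_rate, 0.4, tolerance = 1e-2)
})

test_that("windowed mean rate brackets the trough and degenerates to the point value", {
  prof <- smooth_and_differentiate(exp_curve(0.3))
  expect_equal(windowed_mean_rate(prof, od_at_min = 0.4), 0.3, tolerance = 1e-2)
  expect_equal(windowed_mean_rate(prof, od_at_min = 0.4, 0, 0), 0.3,
               tolerance = 1e-2)

  p <- diauxic_params(noise_sd = 0)
  cur <- gen_diauxic_curve(p)
  prof2 <- smooth_and_differentiate(cur)
  loc <- lag_locus(prof2)
  wr <- windowed_mean_rate(prof2, loc$od_at_min)
  expect_gt(wr, loc$min_rate)
  expect_lt(wr, max_rate(cur))
  expect_error(windowed_mean_rate(prof2, loc$od_at_min, 0.001, 0.001),
               "fewer than 2")
})

test_that("fitness variability is the HG-to-variable-media geometric-mean ratio", {
  same <- list("HG" = 0.8, "LG" = 0.8, "LG+Mal" = 0.8, "LG+Gal" = 0.8)
  expect_equal(fitness_variability(same)$fitness_variability, 1)

  mixed <- list("HG" = 0.9, "LG" = 0.3, "LG+Mal" = 0.9, "LG+Gal" = 0.6)
  expect_equal(fitness_variability(mixed)$fitness_variability,
               0.9 / (0.3 * 0.9 * 0.6)^(1 / 3), tolerance = 1e-12)

  expect_error(fitness_variability(mixed[-2]), "LG")
  mixed$LG <- 0
  expect_error(fitness_variability(mixed), "positive")
})

test_that("resampled variability matches exhaustive enumeration over replicate combinations", {
  reps <- list("HG" = c(0.9, 0.8), "LG" = c(0.3, 0.5),
               "LG+Mal" = c(0.85, 0.9), "LG+Gal" = c(0.55, 0.65))
  # single replicate per condition: no resampling variance
  one <- lapply(reps, `[`, 1)
  r1 <- resample_variability(one, n_resamples = 50, seed = 1)
  expect_equal(r1$sd, 0)
  # exhaustive oracle over the 16 equally likely combinations
  combos <- expand.grid(lapply(reps, seq_along))
  fv <- apply(combos, 1, function(idx) {
    draw <- mapply(function(v, i) v[i], reps, idx, SIMPLIFY = TRUE)
    fitness_variability(as.list(draw))$fitness_variability
  })
  pop_mean <- mean(fv)
  pop_sd <- sqrt(mean((fv - pop_mean)^2))
  rs <- resample_variability(reps, n_resamples = 5000, seed = 99)
  expect_lt(abs(rs$mean - pop_mean), 3 * pop_sd / sqrt(5000) + 1e-9)
  expect_lt(abs(rs$sd - pop_sd), 0.05 * pop_sd + 0.005)
  # determinism
  rs2 <- resample_variability(reps, n_resamples = 5000, seed = 99)
  expect_identical(rs$values, rs2$values)
})

test_that("minimal growth rate correlates positively with GMR across a strain panel", {
  panel <- gen_strain_panel(seed = 42)
  stats_ <- vapply(seq_along(panel), function(i) {
    cur <- gen_diauxic_curve(panel[[i]]$curves$LG, seed = 100 + i,
                             strain = panel[[i]]$name, condition = "LG")
    s <- growth_summary(cur)
    c(s$gmr, s$min_rate)
  }, numeric(2))
  expect_gt(stats::cor(stats_[1, ], stats_[2, ]), 0)
})
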