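# Stochastic lag-phase competition simulator.

zero_lag <- lag_spec("normal", mean_h = 0, sd_h = 0)

test_that("lag specs validate their parameters", {
  expect_error(lag_spec("uniform", lo_h = 5, hi_h = 2), "lo_h < hi_h")
  expect_error(lag_spec("empirical", sample = numeric(0)), "non-empty")
  expect_error(lag_spec("normal", mean_h = 5, sd_h = 1, viable_frac = 1.2),
               "viable_frac")
  expect_error(strain_params("x", -1, 0.2, zero_lag), "non-negative")
})

test_that("lag draws follow the requested distribution and viability", {
  set.seed(1)
  d <- draw_lags(lag_spec("normal", mean_h = 5, sd_h = 0), 100)
  expect_true(all(d$tau == 5))

  set.seed(2)
  du <- draw_lags(lag_spec("uniform", lo_h = 2, hi_h = 10), 1e5)
  expect_lt(abs(mean(du$tau) - 6), 0.03)  # 4 sigma of the MC mean
  expect_true(all(du$tau >= 2 & du$tau <= 10))

  set.seed(3)
  dv <- draw_lags(lag_spec("normal", mean_h = 5, sd_h = 1, viable_frac = 0.5),
                  1e5)
  expect_lt(abs(mean(dv$status) - 0.5), 3 * sqrt(0.25 / 1e5))

  set.seed(4)
  de <- draw_lags(lag_spec("empirical", sample = c(1, 4, 9)), 1e4)
  expect_true(all(de$tau %in% c(1, 4, 9)))
})

test_that("single-strain lag-phase dynamics have the exact degenerate limits", {
  cfg <- sim_config(seed = 5, n_cells = 1000)
  all0 <- strain_params("x", 0.4, 0.3, zero_lag)
  lp <- simulate_lag_phase(all0, 5, cfg)
  expect_equal(lp$N, 1000 * exp(0.3 * lp$time_h), tolerance = 1e-12)

  dead <- strain_params("x", 0.4, 0.3,
                        lag_spec("normal", mean_h = 5, sd_h = 1,
                                 viable_frac = 0))
  lp2 <- simulate_lag_phase(dead, 5, cfg)
  expect_true(all(lp2$N == 1000))
})

test_that("agent-based lag dynamics converge to the lag-CDF quadrature oracle", {
  cfg <- sim_config(seed = 11)
  spec <- lag_spec("normal", mean_h = 4, sd_h = 1.5, viable_frac = 0.95)
  st <- strain_params("x", 0.4, 0.28, lag = spec)
  lp <- simulate_lag_phase(st, 12, cfg)
  oracle <- 50000 * lag_factor_oracle(spec, 0.28, lp$time_h)
  expect_lt(max(abs(lp$N / oracle - 1)), 0.01)
})

test_that("identical strains keep their initial proportions exactly", {
  arch <- archetype_strains()
  twin <- arch$generalist
  twin$name <- "twin"
  sched <- env_schedule(c("maltose", "glucose", "maltose"), c(6, 10, 6))
  sim <- simulate_schedule(list(arch$generalist, twin), sched,
                           c(0.53317, 1 - 0.53317), sim_config(seed = 2))
  expect_true(all(abs(sim$p[, 1] - 0.53317) < 1e-12))
})

test_that("with zero lags the competition reduces to exact exponential dynamics", {
  a <- strain_params("a", 0.45, 0.32, zero_lag)
  b <- strain_params("b", 0.35, 0.22, zero_lag)  # rate deficit 0.1 everywhere
  sched <- env_schedule(rep(c("maltose", "glucose"), 3), rep(c(4, 8), 3))
  sim <- simulate_schedule(list(a, b), sched, c(0.5, 0.5), sim_config(seed = 3))
  lgt <- log(sim$p[, 1] / sim$p[, 2])
  expect_lt(max(abs(lgt - (lgt[1] + 0.1 * sim$time_h))), 1e-9)
  # multi-segment exponential closed form for N itself
  expect_equal(sim$N[, 1],
               0.5 * 50000 * exp(cumsum(c(0, diff(sim$time_h)) *
                 ifelse(sim$time_h <= 4 |
                          (sim$time_h > 12 & sim$time_h <= 16) |
                          (sim$time_h > 24 & sim$time_h <= 28),
                        0.32, 0.45))),
               tolerance = 1e-9)
})

test_that("simulation results are normalized, within-segment non-decreasing, and seed-stable", {
  arch <- archetype_strains()
  sched <- env_schedule(c("maltose", "glucose"), c(8, 16))
  cfg <- sim_config(seed = 17, n_cells = 20000)
  sim <- simulate_schedule(list(arch$generalist, arch$specialist), sched,
                           c(0.5, 0.5), cfg)
  expect_true(all(abs(rowSums(sim$p) - 1) < 1e-12))
  expect_true(all(diff(rowSums(sim$N)) > -1e-9))
  sim2 <- simulate_schedule(list(arch$generalist, arch$specialist), sched,
                            c(0.5, 0.5), cfg)
  expect_identical(sim$N, sim2$N)
  expect_warning(
    simulate_schedule(list(arch$generalist, arch$specialist),
                      env_schedule("maltose", 0.25), c(0.5, 0.5),
                      sim_config(seed = 1, n_cells = 100)),
    "rounded")
})

test_that("the duration heatmap reduces to known limits and shows a coexistence band", {
  arch <- archetype_strains()
  pair <- list(arch$generalist, arch$specialist)
  cfg <- sim_config(seed = 23, n_cells = 20000)

  # 1x1 grid equals a direct two-segment simulation
  hm1 <- proportion_heatmap(pair, 6, 12, c(0.5, 0.5), cfg)
  sim <- simulate_schedule(pair, env_schedule(c("maltose", "glucose"),
                                              c(6, 12)), c(0.5, 0.5), cfg)
  expect_equal(unname(hm1[1, 1]), unname(sim$p[nrow(sim$p), 1]),
               tolerance = 1e-12)

  # zero maltose: pure glucose competition with a logistic closed form
  g_dur <- c(4, 10, 20)
  hm0 <- proportion_heatmap(pair, 0, g_dur, c(0.5, 0.5), cfg)
  dmu <- arch$generalist$mu_glucose - arch$specialist$mu_glucose
  closed <- 1 / (1 + exp(-dmu * g_dur))
  expect_equal(unname(hm0[1, ]), closed, tolerance = 1e-9)

  # entrywise monotone; the generalist-favored and specialist-favored corners
  # bracket a near-neutral regime (coexistence band)
  hm <- proportion_heatmap(pair, c(2, 5, 8, 12), c(4, 10, 16, 24),
                           c(0.5, 0.5), cfg)
  expect_true(all(apply(hm, 2, function(v) all(diff(v) >= 0))))
  expect_true(all(apply(hm, 1, function(v) all(diff(v) <= 0))))
  dp <- hm - 0.5
  expect_true(any(dp > 0) && any(dp < 0))
})

test_that("empirical lag specs can be built from measured lag tables", {
  tb <- gen_lag_table(lag_spec("normal", mean_h = 6, sd_h = 2,
                               viable_frac = 0.9), n = 500, seed = 31)
  spec <- lag_spec_from_table(tb)
  expect_equal(spec$kind, "empirical")
  expect_equal(spec$viable_frac, lag_summary(tb)$frac_resumed)
  expect_true(all(spec$sample <= 20))
})
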