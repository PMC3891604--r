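# lagfit

Microbial populations facing a switch between carbon sources pass through a
lag phase — a transient slowdown while gene expression reprograms from the
preferred sugar (glucose) to an alternative one (maltose, galactose,
ethanol). How severe that lag is, and how it trades off against the maximal
growth rate in stable glucose, is a heritable, evolvable strategy:
glucose specialists repress alternative-carbon genes tightly and lag long,
generalists keep them leaky and transit smoothly. `lagfit` provides a
tested R toolkit for quantifying these strategies for researchers in
microbial systems biology and experimental evolution:

* **Plate-reader growth metrics** — from OD600 time series: the maximal
  specific growth rate (**MaxR**, the OLS slope of ln OD vs time for OD in
  0.15–0.30), the geometric-mean growth rate across the diauxic shift
  (**GMR** = ln(0.75/0.15)/*t*, with *t* the interpolated transit time
  between OD 0.15 and 0.75), the lag-trough location (minimum of
  d ln OD/dt over the band, from a `smooth.spline` fit at `spar = 0.35`),
  windowed rates around the trough, and a fitness-variability index
  (HG-relative GMR over the geometric mean of the variable-media relative
  GMRs) with replicate-resampling error bars.
* **Censored single-cell lag survival analysis** — Kaplan–Meier escape
  curves, two-group log-rank tests, and Cox proportional-hazards fits
  (Breslow ties) for lag tables censored at the microscopy horizon.
* **A stochastic carbon-cycling competition simulator** — per-cell lag
  times drawn from normal/uniform/empirical distributions with a viable
  fraction, exponential growth after escape, lag-free glucose segments,
  0.1-h steps, 50,000-agent cohorts; plus a regime landscape
  (`proportion_heatmap`) over maltose/glucose duration grids.
* **Competition fitness** — Malthusian (ln fold-change) and relative
  fitness from labeled count tables, with confusion-matrix correction of
  label misclassification.
* **ON/OFF switching dynamics** — per-generation two-state switching rates
  (ON→OFF, OFF→ON) estimated from paired hysteresis series, the dilution
  null *f*·2^(−g), and protein production per generation.
* **Synthetic-data generators** — every input type with exact ground truth
  attached, so each estimator has a recovery test.

## Worked example

```r
library(lagfit)

# a noisy biphasic growth curve with a lag trough injected near OD 0.35
p <- diauxic_params(mu1 = 0.45, mu2 = 0.20, od_shift = 0.247,
                    trough_rate = 0.05, noise_sd = 0.01)
curve <- gen_diauxic_curve(p, seed = 42, strain = "YS4", condition = "LG+Gal")
growth_summary(curve)
#> <growth_summary> well synthetic (YS4, LG+Gal)
#>   MaxR 0.3929 /h  GMR 0.1783 /h  GMR/MaxR 0.454
#>   band transit 2.42-11.45 h  min rate 0.0139 /h at OD 0.357
```

The curve grows at 0.45/h on glucose but spends 9 h transiting OD
0.15–0.75, so its average (geometric-mean) rate across the shift is only
0.178/h — 45% of its maximum. The rate minimum is found at OD 0.357, right
where the generator injected the trough (true center 0.349). MaxR reads
0.393 rather than 0.45 because deceleration begins at OD 0.247, inside the
regression band — exactly the bias real decelerating curves show.

```r
# a short-lag generalist vs a 28%-faster glucose specialist:
# 8 h maltose then 16 h glucose
arch <- archetype_strains()
sim <- simulate_schedule(list(arch$generalist, arch$specialist),
                         env_schedule(c("maltose", "glucose"), c(8, 16)),
                         init_props = c(0.5, 0.5), sim_config(seed = 1))
sim
#> <sim_result> 2 strains, 241 time points over 24.0 h
#>   final proportions: generalist 0.3954, specialist 0.6046
```

Under this regime the generalist's short lag does not compensate the
specialist's glucose advantage; stretching the maltose leg (or shrinking
the glucose leg) flips the outcome, and `proportion_heatmap()` maps the
whole regime landscape including the near-neutral coexistence band.

```r
# Cox fit: genotype effect on the hazard of escaping the lag phase
tb <- gen_cox_lag_table(800, beta = 1, seed = 6)
cox_fit(tb, "genotype")
#> <cox_result>
#>   genotype: beta = 0.9447 (se 0.0771), HR = 2.572, p = 1.7e-34

# per-generation switching rates from a sampled hysteresis experiment
hs <- gen_on_fraction(0.05, 0.02, 0.95, 0.05, generations = 10,
                      n_cells = 10000, seed = 3)
estimate_switch_rates(hs$on, hs$off)
#> <switch_rates> a (ON->OFF) = 0.05108, b (OFF->ON) = 0.0204 per generation
#>   lambda = 0.9285, stationary ON fraction = 0.2855, SSE = 0.000224
```

Both estimators recover their generating parameters (hazard ratio e^1 ≈
2.72; switching rates 0.05/0.02) within sampling error.

See `vignettes/lag-phase-fitness.Rmd` for the models, assumptions, design
decisions and limitations.

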