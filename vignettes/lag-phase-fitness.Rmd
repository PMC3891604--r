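---
title: "Quantifying lag-phase growth strategies in stable and fluctuating carbon environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lag-phase growth strategies}
  %\VignetteEncoding{UTF-8}
---

# The scientific problem

When a budding-yeast culture exhausts glucose it must transcriptionally
reprogram to consume a nonpreferred carbon source (maltose, galactose,
ethanol). During this diauxic shift growth slows — the *lag phase* — and the
severity of the slowdown varies enormously across genotypes. Strains with
stringent catabolite repression grow fastest in stable glucose but pay a
long lag when the environment changes; strains with leaky or stochastic
expression of the alternative-carbon (MAL) genes transit the shift smoothly
at the cost of a lower maximal rate. `lagfit` implements the quantitative
machinery for studying this tradeoff at three levels: population growth
curves, censored single-cell lag times, and head-to-head competition in
carbon-cycling regimes.

# Population-level metrics

## Model and definitions

Each well's OD600 series is smoothed with a cubic smoothing spline
(`stats::smooth.spline`), and the specific growth rate is the derivative of
the log-transformed smoothed curve, $\mu(t) = \mathrm{d}\ln \mathrm{OD}/\mathrm{d}t$,
analyzed as a function of population size (OD). Two scalar summaries drive
everything downstream:

* **MaxR** — the maximal specific growth rate on glucose: the OLS slope of
  $\ln \mathrm{OD}$ versus time over samples with OD in $[0.15, 0.30]$.
* **GMR** — the geometric-mean growth rate across the shift:
  $\ln(0.75/0.15)/(t_{0.75} - t_{0.15})$, where the crossing times of the
  OD bounds are interpolated from the curve. GMR can approach but never
  exceed MaxR; their ratio measures how efficiently a strain transits the
  diauxic shift.

The lag trough is located as the minimum of $\mu$ over OD in
$[0.15, 0.75]$. When the minimum sits at the top of the band the rate never
re-accelerated inside it: the curve is flagged lag-free and the OD at the
minimum is reported as 0.75. The *fitness variability* index is the
MaxR-normalized GMR in stable high glucose divided by the geometric mean of
the normalized GMRs in the three variable media (LG, LG+maltose,
LG+galactose); its resampling error draws one biological replicate per
condition per resample.

## Parameter choices

* `spar = 0.35` — the smoothing parameter passed to `smooth.spline`,
  appropriate for 15-min sampling with ~1% multiplicative OD noise. It is
  exposed in every profile-based function. Whether one smooths before or
  after log-transforming is nearly immaterial at this noise level; this
  package smooths the OD itself and differentiates the log of the smoothed
  interpolant.
* Crossing times use monotone Hermite interpolation (`monoH.FC`) restricted
  to a bracketing window around the first upward crossing of each bound.
  Restricting the window makes the interpolation robust to plateau noise and
  settling artifacts; when OD crosses a bound more than once the first
  upward crossing is used and a warning is raised.
* The no-lag call uses a relative rate-drop threshold (`trough_tol`,
  default 2%): in-band rate variation below it is smoothing jitter, not a
  trough. Noiseless exponential curves show < 0.1% in-band variation, real
  lag troughs drop the rate several-fold.
* OD values are used as-is; an affine OD-to-density calibration can be
  applied upstream by the caller. Rates are per hour throughout, OD is
  dimensionless.

# Censored single-cell lag analysis

Single-cell lags (time from carbon transfer to first budding) are censored
at the microscopy horizon (default 20 h); cells that never bud are censored,
not excluded. Escape curves are Kaplan-Meier product-limit estimates, group
comparisons use the two-group log-rank test, and covariate effects are Cox
proportional-hazards fits. These standard estimators are delegated to the
`survival` package behind the package's interface; the test suite
cross-checks them against independent brute-force oracles (explicit
risk-set enumeration and a partial-likelihood grid search).

Ties are handled by the Breslow approximation (Efron available), the
simplest well-defined choice at 15-60-min scoring resolution. Summary
moments (mean, SD, quartiles, noise = SD/mean) are computed over events
only, with the censoring information carried separately by the fraction of
cells that resumed growth within the horizon. Cox fits accept one or two
covariates; no stepwise selection is offered.

# The carbon-cycling competition simulator

Each strain is a genotype: adapted growth rates $\mu_{\mathrm{glu}}$,
$\mu_{\mathrm{mal}}$ and a lag-time distribution (normal truncated at zero,
uniform, or empirical resampling of measured lags) plus a viable fraction.
On every entry into maltose, each of $n$ agent cells (default 50,000) draws
a lag $\tau$ and a viability status; a viable cell sits at size 1 until
$t = \tau$ and then grows exponentially at $\mu_{\mathrm{mal}}$. Glucose
entries are lag-free: the whole population grows at $\mu_{\mathrm{glu}}$.
Time advances in 0.1-h steps; population sizes are real-valued, so the lag
draws are the only stochasticity.

Design choices where the formulation was genuinely open:

* **Re-entries redraw lags.** Each fresh maltose episode draws an
  independent 50,000-agent cohort whose aggregate growth factor rescales the
  strain's current population size — there is no memory mechanism across
  cycles.
* **Cells still lagging when glucose returns grow immediately**, and
  non-viable cells are treated as viable again on glucose entry; viability
  is defined only within a single maltose episode's horizon. The ~10%
  glucose-reentry growth penalty observed for maltose-committed cells is
  deliberately *not* part of the model.
* **Common random numbers across strains.** Within a maltose segment every
  strain's cohort is drawn from an identically seeded stream derived from
  the configuration seed and the segment index. Marginal distributions are
  unchanged, strain contrasts have reduced Monte-Carlo variance, and
  identically parameterized strains receive identical draws, making the
  symmetry argument (identical strains keep their initial proportions)
  hold exactly rather than within sampling error.
* No resource dynamics, dilution events, mutation, or sub-exponential
  growth within segments.

At $n = 50{,}000$ the agent dynamics track the deterministic lag-CDF
integral $N(t)/n = (1 - v) + v\,[1 - F(t) + \int_0^t e^{\mu (t - s)}\,
\mathrm{d}F(s)]$ to well under 1% relative deviation for normal, uniform
and empirical lag kinds (measured at ~0.4-0.5%).

The shipped `archetype_strains()` pair — a short-lag generalist with a
normal lag distribution versus a glucose specialist growing 28% faster in
glucose but with long, heterogeneous uniform lags — is an illustrative
reconstruction from published qualitative facts; the original experimental
parameter values are not available in machine-readable form, so the
landscape over cycling regimes is reproduced qualitatively (dominance
regions and a coexistence band), not numerically.

# Competition fitness from labeled counts

Observed label counts are corrected by inverting the 2x2 confusion matrix
$[[1-e_{rq}, e_{qr}], [e_{rq}, 1-e_{qr}]]$ estimated from single-strain
control cultures (rates are validated to $[0, 0.5)$ so the matrix is
invertible; negative corrected counts, possible near zero, are clipped with
a warning). Malthusian fitness is the natural-log fold change of a
subpopulation (plated total density times corrected label fraction) over
the competition episode; relative fitness is the query/reference ratio, in
which any duration normalization cancels, so none is applied.

# ON/OFF switching dynamics

The population ON fraction of a positive-feedback gene circuit follows the
two-state per-generation chain $f_{t+1} = f_t(1-a) + (1-f_t)b$, closed form
$f_g = f_\infty + (f_0 - f_\infty)\lambda^g$ with
$f_\infty = b/(a+b)$, $\lambda = 1-a-b$. Hysteresis experiments start
paired cultures ON-pregrown and OFF-pregrown; the difference of their
trajectories decays as $\lambda^g$, so the endpoint difference ratio gives
$\lambda$ and the shared stationary fraction gives $b/(a+b)$. The default
estimator uses only the endpoints (exactly identified); a bounded
least-squares variant uses all points when more are available. The dilution
null $f_0 2^{-g}$ and the production-per-generation excess over it
(`production_rate`) quantify whether a signal decays passively or is
actively synthesized. ON/OFF classification thresholds are an input (the
instrument- and reporter-specific cutoff is a reader-level concern);
generation counts are conversions from population fold change,
$g = \log_2(N_\mathrm{final}/N_\mathrm{initial})$, done by the caller.

# The synthetic-data generator

Every input type can be generated with known ground truth:

* **Diauxic curves** come from a rate-versus-OD function — constant $\mu_1$
  below the shift OD, a half-cosine dip to a trough rate centered half the
  dip width (in doublings) above it, recovery to $\mu_2$, and a roll-off
  approaching the stationary plateau — integrated by quadrature of
  $\mathrm{d}t = \ln 2\,\mathrm{d}x/\mu(x)$ in doubling space, sampled at
  the plate-reader cadence, with lognormal noise. Because the population
  metrics are defined in rate-vs-OD space, crossing times, GMR and trough
  location are exact by construction and attached as the `truth` attribute
  (the MaxR truth is the regression estimand evaluated on the noiseless
  sampled curve, so estimator and truth share a definition).
* **Lag tables** draw from any `lag_spec`, censoring at the horizon; a
  separate generator produces two-group exponential lags with a known
  hazard ratio for Cox recovery tests.
* **Competition counts** run the simulator, sample labels binomially at the
  cytometer event depth, and pass them through the forward confusion
  channel.
* **Hysteresis series** iterate the switching chain with binomial sampling
  of the population propagated per generation.
* The 18-strain panel spans short-lag/low-MaxR to long-lag/high-MaxR
  archetypes with an imposed positive mean-lag/SD-lag relationship and a
  viable fraction declining with lag — the phenotype structure observed
  across natural isolates — so correlation-style properties can be asserted
  on data where the generator imposes them.

Defaults emulate the study conditions these tools are built for: 15-min
OD sampling, OD analysis band 0.15-0.75, MaxR band 0.15-0.30, 20-h
microscopy horizon, 0.1-h simulation steps, 50,000-cell cohorts, 24-h lag
viability horizon, and cytometry misclassification rates of order 1/5,000.

## What the synthetic suite does and does not show

The generators reproduce the *structure* of the real data (biphasic rate
profiles, censored heterogeneous lags with a nonviable fraction,
exponential competition under alternating carbon segments, per-generation
switching) but not instrument-specific artifacts: evaporation and edge-well
drift, OD nonlinearity outside the calibrated range, scoring-resolution tie
patterns, cytometer gating drift, or growth-rate costs of expression state
carried across environments. Passing recovery tests therefore validates the
estimators' correctness under the stated models, not robustness to every
artifact of a particular instrument.

# Numerical choices and problem sizes

Tolerances asserted in the test suite follow from explicit error budgets:
interpolation-limited checks at 1e-3 or better, closed-form identities at
1e-6 to 1e-12, Monte-Carlo checks at 3 standard errors of the relevant
estimator (binomial SEs for sampled fractions, delta-method SEs with
per-generation variance propagation for switching rates, quadrature oracles
for the simulator). Calibration checks use 1,000 null log-rank simulations
at n = 200 per group and 200 Cox recovery fits at n = 500 — sizes at which
the test suite and the acceptance script each complete in well under a
minute on one CPU. Degenerate inputs are defined rather than left to
chance: zero-width rate windows return the point rate, zero-length schedule
segments are skipped, constant hysteresis series yield zero switching
rates, and all-censored lag tables report undefined moments with a zero
resumed fraction.

# Known limitations

* The Cox/log-rank machinery reports raw p-values; multiple-testing
  correction across strain pairs is the caller's responsibility.
* The smoothing-spline rate profile is unreliable in the first and last few
  samples of a curve (boundary effects); all analyses restrict to the OD
  band, where the derivative is accurate to ~1e-3 on noiseless data.
* The simulator has no demographic stochasticity beyond lag draws, so it
  understates proportion variance at small population sizes.
* The endpoint switching-rate estimator requires the two initial conditions
  to differ; series without contrast (or whose endpoint gap exceeds the
  initial gap) are rejected as inconsistent with any two-state chain.
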