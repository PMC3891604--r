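Package: lagfit
Title: Diauxic Lag-Phase Fitness Metrics and Carbon-Switching Competition Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies microbial growth strategies across stable and
    fluctuating carbon environments. Computes population-level fitness
    metrics from plate-reader OD600 time series (maximal specific growth
    rate, geometric-mean growth rate across the diauxic shift, lag-phase
    trough location, and a fitness-variability index with resampling
    errors); summarizes and tests censored single-cell lag-time data with
    Kaplan-Meier curves, log-rank tests and Cox proportional-hazards fits;
    simulates stochastic two-strain competition across maltose/glucose
    cycling regimes with per-cell lag-time draws; computes Malthusian and
    relative fitness from labeled competition counts with misclassification
    correction; and estimates per-generation ON/OFF expression-switching
    rates from hysteresis experiments. A synthetic-data generator produces
    every input type with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
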