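Package: simonlca
Title: Leaky Competing Accumulator Models of the Simon Effect
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and fitting of extended leaky competing accumulator
    (LCA) models for conflict tasks with unequal response frequencies.
    Provides a trial-level stochastic simulator with a transient,
    sign-reversing automatic input and model variants for biased response
    preparation, attention shifts, location-congruency contingencies and
    shielding of prepared responses; reaction-time distribution tools
    (outlier screening, quantiles, delta plots with orthogonal-polynomial
    coefficients, cross-participant pooling with a robust scale estimator);
    experiment-design utilities including noncentral-t power computations;
    and a two-stage quantile/G-squared fitting procedure with AIC model
    comparison, simulation-based prediction intervals and a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
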