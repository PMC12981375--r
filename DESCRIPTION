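Package: synthsales
Title: Synthetic-Control Evaluation of Brand-Level Weekly Sales Panels
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the causal effect of a market intervention on one
    brand's weekly unit sales with the synthetic control method. Provides
    long-format panel ingestion with sub-brand aggregation and complete-case
    filtering, pre-intervention-window standardization (z-score, min-max,
    robust), exact simplex-constrained donor-weight estimation, in-space
    placebo permutation inference based on post/pre mean-squared-error
    ratios with week-specific p-values, back-transformation of standardized
    gaps into cumulative and percent unit-scale effects, a sensitivity
    harness across standardization methods, and a heavy-tailed synthetic
    scanner-panel generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
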