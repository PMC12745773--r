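Package: heatmort
Title: Distributed-Lag Heat-Mortality Models with Temporal Compounding and
    Counterfactual Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying heat-wave mortality from department-day
    panels of daily deaths and weather. Fits distributed-lag polynomial
    exposure-response functions for log mortality rates with two-way
    (department-by-year and department-by-day-of-year) fixed effects,
    optional interactions between each day's temperature and the previous
    day's temperature (temporal compounding) and with long-term mean
    climate, department-clustered covariance, and multivariate-normal
    coefficient sampling for uncertainty propagation. Includes excess
    mortality baselines, climatological event prediction, counterfactual
    temperature scenarios via region-wide daily deltas, attributable-death
    accounting, and a synthetic panel generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
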