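Package: npsamp
Title: Nonparametric Sampling of Times to Event from Discretized Hazards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Draws times to events from arbitrary, possibly covariate-driven
    hazards in individual-level simulation models (discrete-event simulation,
    microsimulation). A hazard is discretized on a uniform time grid into a
    categorical distribution over intervals; interval draws are corrected back
    to continuous time with a uniform within-interval offset. Supports
    univariate sampling from a single hazard and vectorized multivariate
    categorical sampling across heterogeneous individuals, proportional-hazards
    covariate effects with time-independent or time-dependent covariates
    (including Gaussian random-walk covariate paths), parametric baseline
    hazards (exponential, gamma, log-normal, Gompertz, Weibull) with analytic
    means and direct inverse-cumulative-hazard sampling as comparators, and
    conversion of life tables (qx or mx) to hazard grids, with a synthetic
    life-table generator for fully reproducible examples.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
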