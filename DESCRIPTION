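Package: socfit
Title: Inverse Modeling of Soil Organic Carbon Pool Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A surrogate of the CENTURY soil-organic-carbon sub-model for
    agricultural soils: monthly forward simulation of litter and soil
    organic matter pools with first-order decay kinetics and Euler or
    Crank-Nicolson integration, yield-based estimation of above- and
    belowground carbon inputs from harvest indices, multiplicative
    management effects (tillage, nitrogen fertilization, organic
    amendment) on decay of the active and slow pools, nonlinear
    least-squares calibration of initial pool fractions and management
    multipliers against sparse dated SOC observations, Monte-Carlo
    propagation of parameter uncertainty to prediction intervals, a
    Michaelis-Menten substrate-dependent decay variant, and a generator
    of synthetic multi-site long-term experiments for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    minpack.lm,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
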