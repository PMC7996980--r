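Package: minmodex
Title: Exercise-Extended Minimal Models of Glucose Dynamics in Type 1 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Six exercise-extended variants of the Bergman Minimal Model of
    glucose-insulin kinetics for individuals with type 1 diabetes, with
    compiled ODE simulation under measured insulin and oxygen-uptake forcing,
    Bayesian parameter estimation by adaptive random-walk Metropolis MCMC,
    model comparison by the deviance information criterion (DIC), seeded
    virtual-patient cohort generation, and an in-silico protocol engine for
    exercise management studies (pre-meal bolus reductions and pre-exercise
    basal reductions) with glycemic time-in-range outcome reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
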