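Package: incitrend
Title: Incidence Trends of Chronic Diseases from Prevalence Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates age-specific incidence rates of irreversible (chronic)
    diseases, and secular trends therein, from a series of cross-sectional
    prevalence surveys combined with general and relative mortality, using the
    illness-death model's partial differential equation along cohort
    characteristics. Provides a direct inversion estimator and a weighted
    nonnegative least-squares estimator, a Runge-Kutta forward simulator of
    prevalence surfaces for validation, binomial survey-noise modelling with
    percentile-bootstrap confidence bounds, and a Danish-diabetes-like
    validation scenario (male population, ages 30+, 1995-2004).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, optparse, yaml
Suggests: testthat (>= 3.0.0), deSolve, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
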