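Package: idmprev
Title: Illness-Death Model Projection of Chronic Disease Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Projects the age- and sex-specific prevalence of a chronic
    condition (built around type 2 diabetes in Germany) with the
    illness-death model.  The prevalence partial differential equation is
    integrated along age-time characteristics with a classical
    fourth-order Runge-Kutta scheme, using the mortality-rate-ratio
    substitution so that only general-population mortality, the mortality
    rate ratio and incidence are required as inputs.  Includes a natural
    cubic spline regression for age-period-sex incidence trends fitted to
    grouped incidence estimates, scenario machinery for freezing or
    extrapolating those trends, conversion of prevalence to population
    case counts and summary tables, a synthetic-data generator with known
    ground truth emulating claims-based inputs, and an independent
    discrete-time cohort microsimulation used as a numerical oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
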