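Package: plateletfda
Title: Functional Data Analysis of Platelet Aggregation Kinetics
Version: 0.1.0
Authors@R:
    person("Platelet", "Kinetics Lab", email = "maintainer@plateletfda.org",
           role = c("aut", "cre"))
Description: Tools for analysing optical platelet-aggregometry time courses as
    functional data. Percent-aggregation traces are smoothed with penalized
    truncated power-basis splines in their linear mixed-model formulation
    (REML variance components, BLUP coefficient prediction), giving estimates
    of the mean aggregation curve and of its first (velocity) and second
    (acceleration) derivatives with pointwise confidence bands. A joint
    multi-condition model with dose-indicator deviation curves supports
    contrasts between matched agonist-only and agonist-plus-nanoparticle
    conditions ("nano effect" curves). The empirical aggregation law dy/dt =
    F(y) is reconstructed by regressing predicted velocity on predicted
    aggregation, either linearly or with a smooth penalized-spline law, with
    steady-state location and local stability analysis. A synthetic
    aggregometry-data generator with analytically tractable curve families
    supports validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
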