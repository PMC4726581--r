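Package: bmesoil
Title: Bayesian Maximum Entropy Mapping of Soil CO2 Efflux with
    Temperature-Derived Soft Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geostatistical estimation of the spatial distribution of soil
    respiration (CO2 efflux) on small plots.  Sparse flux measurements (hard
    data) are fused with dense soil-temperature readings converted into
    probabilistic soft data through an Arrhenius-type flux-temperature
    regression with Student-t prediction intervals.  Implements empirical
    auto- and cross-variograms with Gaussian and spherical model fitting,
    ordinary kriging and cokriging, a Bayesian Maximum Entropy (BME) engine
    with a maximum-entropy Gaussian prior and numerical posterior densities,
    a Gaussian random-field simulator for coupled temperature/flux fields,
    hold-out validation statistics, and a sampling-density experiment
    comparing BME against kriging under shrinking designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
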