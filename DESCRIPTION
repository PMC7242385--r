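Package: zoifacil
Title: Zone-of-Influence Simulation of Density-Dependent Plant Facilitation
    Under Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit individual-based model of plant-plant
    interactions on a wrap-around patch grid. Each plant holds a circular
    zone of influence (ZOI) allometrically tied to its biomass; overlapping
    ZOIs divide both contested resources (mode-of-competition exponent p)
    and stress amelioration (mode-of-facilitation exponent q) among
    neighbours, with a size-dependent facilitative response entering the
    growth equation through the realized-stress index. Includes the
    relative interaction index (RII) against a lone-plant baseline, a full
    factorial stress-by-density experiment runner, curve-shape diagnostics
    (hump detection, peak density), and a Bayesian linear-model comparison
    backend (Gibbs sampling, split R-hat, WAIC, model averaging) for
    relating RII to stress and density.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
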