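Package: purefrag
Title: Simulation and Inverse Problems for the Pure Fragmentation Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the size-structured pure fragmentation equation that
    describes the division of protein filaments such as amyloid fibrils.
    Provides a conservative implicit solver on a logarithmic size grid, a
    discrete monomer-resolved companion model, closed-form reference
    solutions, observables (normalized length distributions, moments,
    self-similar rescaling, numeric Mellin transforms), inversion of the
    division-rate parameters gamma and alpha and of the fragmentation
    kernel kappa from time series of length distributions, two-sample
    Kolmogorov-Smirnov kernel discrimination, and seeded synthetic
    fragmentation experiments emulating nano-imaging length measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
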