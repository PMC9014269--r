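Package: cropideo
Title: Crop Ideotype Design by Individual-Based Crop-Weed Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale pipeline for simulation-based crop ideotyping,
    developed around pea (Pisum sativum L.) and annual arable weeds.
    Parameterizes varieties from individual-plant garden-plot measurements
    (power-law allometry and exponential shade response, interpolated to 11
    BBCH stages), generates virtual varieties by correlation-constrained
    Latin hypercube sampling, samples cropping systems under agronomic
    constraints, runs a daily individual-based crop-weed competition
    simulator with paired weedy/weed-free runs, computes yield and weed
    (dis)service indicators, and identifies key parameters and optimal
    parameter-by-management combinations with multivariate regression trees
    with surrogate splits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    lhs,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
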