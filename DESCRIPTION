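Package: oleoflux
Title: Constraint-Based Modeling of Lipid Accumulation in Oleaginous Yeast
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Flux balance analysis (FBA) machinery for genome-scale metabolic
    models of oleaginous yeasts, built around the trade-off between citrate
    overflow and triacylglycerol (TAG) storage in Yarrowia lipolytica. Reads
    and writes COBRA-dialect SBML Level 2 models, solves FBA with parsimonious
    flux resolution, flux variability analysis, robustness scans, gene
    deletion screens and dynamic FBA batch simulations, and implements the
    lipid-accumulation analyses specific to oleaginous physiology:
    variable-lipid biomass equations, split growth/non-growth ATP maintenance
    coupled to substrate uptake, fed-batch feed-rate calculation to suppress
    citrate excretion, oxygen-limitation thresholds and the comparison of
    cytosolic NADPH sources. A small hand-verifiable synthetic core model and
    an exhaustive vertex-enumeration oracle make every stage testable without
    external model files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
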