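Package: musselhab
Title: Hydraulic and Landscape Habitat Suitability Modelling for Amazonian Freshwater Mussels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Habitat-suitability analysis for Amazonian freshwater mussels
    (Castalia ambigua, Anodontites elongatus) from near-bed flow and sieve
    granulometry surveys. Computes complex hydraulic variables (Froude,
    Reynolds and boundary Reynolds numbers, shear velocity and stress,
    critical shear stress, stream power) and substrate metrics (mean particle
    size, sorting index, bed roughness) from plot-level measurements; fits
    random-forest habitat and landscape-stressor models with an out-of-bag
    mtry/ntree tuning protocol, a group-bootstrap (repeated-measures)
    variant, permutation importance and partial dependence; characterizes
    mussel spatial pattern with kernel-smoothed intensity, cross-validated
    bandwidth selection and the Hopkins-Skellam clustering test; and provides
    a seeded synthetic river-reach generator emulating the survey design for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
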