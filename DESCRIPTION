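Package: aviandiet
Title: Quantitative Diet and Pedal-Ecology Inference for Fossil Birds
Version: 0.1.0
Authors@R:
    person("Avian", "Ecomorphology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A four-proxy quantitative framework for inferring the diet and
    pedal ecology of fossil birds from body mass, claw traditional
    morphometrics, jaw mechanical-advantage indices, and two-dimensional
    finite-element jaw strength.  Includes phylogenetic comparative
    machinery (Blomberg's K, its multivariate generalisation, and a
    permutation-based pairwise group comparison under a Brownian-motion
    covariance), a plane-strain constant-strain-triangle finite-element
    solver with compositional post-processing of strain fields (the
    intervals method with log-ratio transforms), diet classification from
    percentage diet tables, Youden-index mass cut-points, correlation-matrix
    PCA / LDA / DAPC with independent projection of fossil specimens, and a
    synthetic-data generator so the whole pipeline runs with no external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
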