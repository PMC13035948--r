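Package: flowgof
Title: Spatial Goodness-of-Fit Testing for Origin-Destination Flow Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based evaluation of the spatial accuracy of
    origin-destination flow models, with migration systems as the motivating
    application. Bilateral flow panels are modelled by Poisson
    pseudo-maximum-likelihood (PPML) regression with origin, destination and
    year fixed effects and multiway cluster-robust covariance; ensembles of
    complete synthetic flow systems are simulated from the fitted model by
    independent truncated-normal draws per dyad with optional row-sum
    calibration; each system is summarised by spatial concentration indices
    (aggregate coefficient of variation, Gini, migration inequality) and flow
    reciprocity; and the observed system is compared with the ensemble through
    envelope coverage and Mahalanobis distances for per-location inflow or
    outflow profiles and individual corridors. A known-truth synthetic panel
    generator supports calibration and power studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    jsonlite,
    withr
Config/testthat/edition: 3
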