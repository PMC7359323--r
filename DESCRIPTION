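Package: granumix
Title: Granular Mixing Simulation, Endpoint Forecasting and Surrogate Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale discrete element method (DEM) simulation of cohesive
    particle mixing in an agitated filter dryer, contact-based segregation-index
    metrics, ARIMA forecasting of the time to uniform mixing, and surrogate
    (machine-learning) models that map material and process descriptors to the
    forecast mixing time. Includes synthetic mixing-curve and design-table
    generators so every downstream stage can be exercised without running DEM,
    plus an end-to-end pipeline driver and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lhs,
    randomForest,
    e1071,
    glmnet,
    mixOmics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
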