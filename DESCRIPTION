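Package: meatmicro
Title: Predictive Microbiological Quality Analysis of Minced Beef
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for monitoring and predicting the microbiological quality
    of minced beef from routine surveillance records. Classifies colony counts
    against m/M microbiological criteria (satisfactory / acceptable /
    unsatisfactory), simulates a three-year Monday/Wednesday/Friday sampling
    design with butcher shift rotation and cold-chain temperatures, fits a
    9-10-4 multilayer perceptron (logistic hidden layer, identity output,
    BFGS on sum-of-squares error) predicting four microbial counts from
    process variables, evaluates fits with reduced chi-squared, RMSE, MBE,
    MPE, r-squared and residual moments, and computes signed Yoon
    connection-weight importances of each process variable for each microbial
    group. Ships a published reference weight set for the sensitivity
    analysis.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
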