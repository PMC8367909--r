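Package: facetlink
Title: Linking Accuracy of Performance Tests Under Many-Facet Rasch Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for studying how accurately two
    performance tests scored by human raters can be linked onto a common scale
    under a many-facet Rasch model (MFRM). Generates synthetic examinee, task,
    rater and category parameters for a base and a new test with configurable
    distribution shifts, embeds common (anchor) raters and tasks, supports
    missing-by-design rater-set assignment and anchor drift, estimates
    new-test parameters by Markov chain Monte Carlo with anchors held fixed
    (fixed common-parameter linking), and evaluates linking accuracy against a
    calibration-based threshold across grids of commonality counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
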