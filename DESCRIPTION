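Package: sedsax
Title: Stochastic Edit Distance Learning for SAX-Encoded Physiological
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts binary patient outcomes from univariate physiological
    time series. Each series is converted to a labeled SAX symbol string
    (overlapping-window z-normalization, piecewise aggregate approximation,
    Gaussian-breakpoint discretization, run collapse, and systematic group
    sampling to a fixed length cap), the costs of a stochastic edit distance
    are learned as the parameters of a conditional memoryless finite-state
    transducer by expectation-maximization over nearest-neighbour string
    pairs, and new series are classified with the 1-nearest-neighbour rule
    under the learned distance. A synthetic cohort generator supports
    end-to-end evaluation without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
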