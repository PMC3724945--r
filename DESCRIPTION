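Package: grnmr
Title: Stochastic Majority-Rule Boolean Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold Boolean gene regulatory networks with stochastic
    tie-breaking under four majority-rule variants (majority, inertial,
    null, and inertial-null). Builds exact finite Markov chains on the
    configuration space with rational arithmetic, classifies attractors as
    terminal strongly connected components, computes fundamental matrices,
    absorption probabilities, stationary distributions and mean return
    times, enumerates and classifies the complete two-node model atlas up
    to isomorphism, and provides a steady-state search and edge-addition
    repair engine demonstrated on the budding-yeast cell-cycle network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
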