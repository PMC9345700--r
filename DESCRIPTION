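Package: cocontagion
Title: Compartmental Dynamics of Co-Circulating Violence and Racism
    Contagion
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for an eight-compartment
    behavioural-contagion model in which violence and racism spread
    through a community like two interacting infectious diseases,
    including a coinfection class with dedicated control rates.  Provides
    the model right-hand sides and the two reduced single-behaviour
    submodels, basic reproduction numbers via next-generation matrices,
    closed-form and numeric equilibria with local stability
    classification from Jacobian eigenvalues, normalized forward
    sensitivity indices of the reproduction numbers, adaptive
    Runge-Kutta trajectory simulation with positivity and boundedness
    monitoring, parameter sweeps, and control-rate scenario experiments.
    Results are returned as tibbles with broom-style tidy() and glance()
    methods and ggplot2 autoplot() visualisations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
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
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
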