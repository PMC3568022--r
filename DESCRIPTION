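Package: inckin
Title: Incremental Parameter Estimation for Power-Law Kinetic Models of
    Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage (incremental) estimation of rate constants and
    kinetic orders in generalized mass action (GMA) models of metabolic
    networks.  Measured concentration time courses are smoothed and
    differenced to give time-slopes; the stoichiometric degrees of freedom
    partition the fluxes into a small independent set, searched by a seeded
    bounded global optimizer, and a dependent set computed algebraically
    from the slopes and then regressed flux-by-flux in logarithmic scale.
    Provides concentration-error and slope-error objectives, an extension
    to unmeasured metabolites, generative in-silico benchmark cases
    (a generic branched pathway and a synthetic surrogate of lactococcal
    glycolysis), broom-style tidiers, ggplot2 plotting methods, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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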