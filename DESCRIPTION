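Package: chaoscope
Title: Discovery and Control of Chaos in Synthetic Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for exploring deterministic chaos in small engineered
    microbial communities grown in a chemostat. The package enumerates the
    combinatorial space of three-strain communities built from quorum-sensing
    (QS) and bacteriocin parts, simulates the resulting ODE models (Monod
    growth, Hill-type bacteriocin killing, QS-regulated expression), estimates
    maximal Lyapunov exponents with a dual-orbit renormalisation method,
    selects oscillatory and chaotic models and parameters by Approximate
    Bayesian Computation with Sequential Monte Carlo, and analyses the winning
    topology through steady-state and bifurcation analysis, parameter scans,
    real-time parameter ramps and random-forest feature importance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
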