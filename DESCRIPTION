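Package: logicess
Title: Reverse Engineering of Logic-Based ODE Signalling Models by
    Cooperative Scatter Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds continuous logic models (BoolCube and normalized HillCube
    transforms of Boolean update functions) of cell-signalling networks from
    signed prior-knowledge graphs, and reverse-engineers both the network
    structure (binary AND-gate selectors) and the kinetic parameters (Hill
    exponents and half-saturations, state life-times) from perturbation
    time-series data.  The mixed-integer estimation problem is solved with an
    enhanced scatter search hybridised with a mixed-integer local search, and
    with a self-adaptive cooperative island scheme in which a master process
    gates solution exchange by an adaptive improvement threshold, keeps a
    scoreboard of island performance, and reconfigures stagnated islands.
    Includes readers and writers for SIF networks and MIDAS-style perturbation
    data, a synthetic-benchmark generator with ground truth, and AIC-based
    model reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
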