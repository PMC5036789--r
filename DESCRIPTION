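Package: netsens
Title: Steady-State Sensitivity Analysis of Signed Signalling Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates signed (activating/inhibiting) signalling networks
    with Hill-type ordinary differential equations and quantifies how the
    basal ("independent") activity of each node controls downstream
    readouts. Ships a curated model of the NPM-ALK fusion-kinase network
    driving anaplastic large cell lymphoma, exhaustive and sampled
    enumeration of binary high/low activity states with a log-log gain
    sensitivity statistic, extreme-sensitivity ranking profiles,
    signal-flow (involvement and amplification-ratio) metrics exportable
    as viewer-ready node attributes, fine-grained sensitivity surfaces
    over continuous activity grids, and seeded generators of random
    signed networks and analytically solvable motifs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    jsonlite,
    yaml,
    igraph,
    deSolve,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
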