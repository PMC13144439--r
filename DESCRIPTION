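Package: sticc
Title: Reversible and Irreversible Cell State Transition Vectors from
    Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers per-cell state transition vectors from single-cell gene
    expression data and a signed regulator-target network, using cross-cell
    correlations between regulator expression in one cell and target
    expression in a nearby cell. Outgoing and incoming vectors are estimated
    by local least-squares regression and decomposed into an irreversible
    net-flow component and a sign-free reversibility component. Includes a
    RACIPE-style ensemble simulator of small gene circuits (shifted-Hill
    ODEs, Euler-Maruyama SDEs, signal schedules, a splicing variant, and a
    quantile dropout model), a sampling-radius optimizer, inverse-distance
    vector-field smoothing, density-based basin estimation, edge-sensitivity
    analysis, and a trajectory-based validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
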