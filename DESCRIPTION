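Package: autocatnet
Title: Topology and Composition of Autocatalytic RNA Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing landscapes of autocatalytic RNA reaction
    networks built from Azoarcus-type ribozyme fragments. Implements the
    parameter-free linear kinetic model of catalyst accumulation (matrix
    exponential of the rate system), centrality-based composition
    predictions, a compositional perturbation statistic for networks
    differing by one catalytic species together with its analytical
    topology-based prediction, landscape-level statistics (rank
    conservation, yield ranking, growth-variation trade-off tests),
    simulation of network-growth trajectories with inflexion and
    catalytic-innovation analysis, a droplet barcoded-sequencing UMI
    count-processing pipeline, and seeded synthetic-data generators that
    emulate the droplet-fusion experiment end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
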