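Package: netsel
Title: Resting-State Network Topology and Task Activation Selectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds resting-state functional connectivity graphs from node-level
    BOLD time series, detects reliable functional systems by bootstrapped
    Infomap consensus across edge densities, classifies connector and
    non-connector nodes from weighted participation coefficients, and relates
    node topology to task activation through a per-participant activation
    selectivity score. Includes motion scrubbing with framewise-displacement
    censoring, and a synthetic-cohort generator that plants block-structured
    correlation matrices, connector roles, age-graded dedifferentiation, motion
    spikes, and task beta maps, so the full pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
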