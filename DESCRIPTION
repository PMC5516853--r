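Package: hopscape
Title: Hopfield Energy Landscapes of Cellular Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies Waddington's epigenetic landscape from stage-annotated
    gene-expression time courses using a Hopfield-network formalism. A
    correlation-weighted, zero-diagonal symmetric network is built over
    feature-selected genes; every sample's ternary expression state is scored
    with the quadratic Hopfield energy, so that tightly co-varying (stable)
    stages sit in low-energy basins and transient stages on high-energy
    ridges. The landscape is rendered as a 3-D surface over the first two
    principal components via inverse-PCA grid scoring, switched driver genes
    are identified between stages, and attractor robustness is assessed by
    progressive perturbation against random-network baselines. A synthetic
    stage-structured data generator with known ground truth supports
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
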