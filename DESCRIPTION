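Package: synconn
Title: Similarity Scores, Compartment Clustering and Multi-Hop Path
    Analysis for Synaptic Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for analysing electron-microscopy
    reconstructions of neural circuits at synaptic resolution, modelled on
    the sensory-to-output wiring of the Drosophila larval feeding system.
    Provides pairwise neuron similarity scores (dotprops-based morphology,
    synapse placement, normalized connectivity), average-linkage
    compartment clustering with dendrogram cutting, thresholded directed
    synaptic graphs built from polyadic connector tables, enumeration of
    1/2/3-hop sensory-to-output paths with layer assignment and
    divergence/convergence statistics, and seeded synthetic-data
    generators that plant recoverable compartment and circuit structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    igraph,
    RANN,
    mclust,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
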