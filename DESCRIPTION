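Package: octlayers
Title: Retinal Layer Annotation of OCT B-Scans via Fuzzy Enhancement and Graph Shortest Paths
Version: 0.1.0
Authors@R: person("OCT Layers", "Developers", email = "octlayers@example.org",
    role = c("aut", "cre"))
Description: Fully automatic annotation of retinal layers in optical coherence
    tomography (OCT) B-scan images. Implements fuzzy histogram hyperbolization
    (FHH) contrast enhancement with automatic, stabilized fuzzifier selection;
    construction of polarity-specific sparse pixel graphs from normalized
    vertical intensity gradients with fuzzified edge weights; and sequential
    shortest-path (Dijkstra) extraction of the 8 interfaces delimiting 7
    retinal layers, using previously found boundaries to limit each search
    region. Includes boundary and region evaluation metrics (MAD, RMSE, Dice,
    accuracy, sensitivity, error rate) and a synthetic B-scan generator with
    known ground truth, multiplicative correlated speckle and vessel shadows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    png,
    tiff,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
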