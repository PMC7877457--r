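Package: synaptopipe
Title: Synapse Segmentation, Classification and Subtype Discovery from
    Multiplexed Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multi-round, multi-channel
    immunofluorescence images of cultured neurons: registration of imaging
    rounds on the MAP2 channel, illumination correction, white top-hat spot
    enhancement, robust-background thresholding, watershed declumping of
    synaptic puncta, rule-based assembly of puncta into synapsin1-anchored
    synapses, excitatory/inhibitory classification, a CellProfiler-style
    shape and intensity feature battery, UMAP embedding with HDBSCAN subtype
    discovery, and replicate-level permutation statistics with BCa bootstrap
    effect sizes. Includes a synthetic multiplexed-image generator with full
    ground truth for validation and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    EBImage,
    igraph,
    stats,
    tools,
    utils,
    tiff,
    yaml
Suggests:
    boot,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
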