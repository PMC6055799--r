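Package: ernet
Title: Quantification of Endoplasmic Reticulum Network Architecture and Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the architecture and dynamics of the cortical
    endoplasmic reticulum (ER) network in fluorescence micrographs. Implements
    the full image-analysis workflow used for plant cortical ER: contrast
    enhancement, trainable three-class pixel segmentation (ER, background,
    rejected organelle signal), connectivity-repairing closing, enclosed
    polygonal-region analysis, cisternae isolation by iterated morphological
    opening, topology-preserving skeletonization with three-way junction and
    endpoint detection, and area-normalized morphometric summaries. Time-lapse
    tools provide persistency (temporal colour-code) composites, cumulative
    fluorescence intensity (CFI) distributions and ratio curves, puncta
    tracking with merge/split/absorption events, and motion classification.
    A synthetic phantom generator produces cortical-ER-like tubule networks
    (planar graphs with three-way junctions and polygonal lacunae), cisternal
    sheets, distractor organelles, confocal-style noise and scripted motion,
    with exact ground truth, so that every stage of the pipeline is verifiable
    without microscope data. Group comparisons use exact/approximate Wilcoxon
    rank-sum and Welch t tests over replicated designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    ranger,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
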