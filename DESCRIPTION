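Package: trijunct
Title: Quantification of Tricellular Tight-Junction Maturity in Epithelial Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic image-analysis pipeline for spatially resolved
    scoring of tricellular tight-junction (tTJ) maturity in confluent
    epithelial monolayers. From multichannel fluorescence images or z-stacks
    (junctional marker such as ZO-1, tricellular marker such as tricellulin,
    and nuclei), the pipeline performs guided block z-projection, noise
    estimation and contrast adjustment, junction-network binarization and
    skeletonization, pixel-counting vertex detection with point-source
    relocation, cell segmentation and polygonization, jamming shape
    descriptors (apical shape index, aspect ratio, density), and a per-vertex
    tricellulin localization score bounded in [0, 1]. Includes a synthetic
    epithelium generator with exact ground truth, wound-front row analyses,
    cell-cycle triplet grouping, Kolmogorov-Smirnov group comparisons, and
    map rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    png
Config/testthat/edition: 3
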