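Package: cardioEM
Title: Segmentation, Generative Modelling and 3D Morphometry of
    Cardiomyocyte Ultrastructure in Volume Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale workflow for quantifying cardiomyocyte
    ultrastructure (mitochondria, myofibrils, Z-discs) in 3D electron
    microscopy stacks. Provides a synthetic cardiomyocyte phantom
    generator with ground-truth labels, a modified U-net semantic
    segmenter with a densely connected bottleneck and trainable linear
    units, segmentation evaluation including border-thinned Rand and
    information-theoretic scores, a label-conditioned style-based
    generative model monitored by Frechet inception distance, assembly
    of generated 2D slices into 3D volumes by Jaccard-distance
    ordering, and 3D morphometrics (sphericity, compactness,
    elongation, flatness, spareness, surface-area-to-volume ratio) with
    sliding-kernel density maps and distribution comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
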