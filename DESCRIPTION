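Package: glomap
Title: Odor Response Map Analysis for Multisite Calcium Imaging of the
    Honey Bee Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for wide-field GCaMP6f calcium-imaging
    recordings of odor responses in the honey bee brain (antennal lobe,
    lateral horn, mushroom body calyx).  Converts raw fluorescence movies
    to delta-F/F response maps (baseline normalisation, frame-median
    illumination and bleaching correction, Gaussian spatial filtering,
    biphasic amplitude extraction), quantifies odor coding through masked
    pixel-wise Euclidean distances, same-versus-different odorant
    comparisons, Ward hierarchical clustering and Mantel matrix tests, and
    provides the matching statistical battery (repeated-measures ANOVA with
    Dunnett many-to-one post hoc tests, Friedman tests, Wilcoxon
    matched-pairs tests, vapor-pressure regression, Fisher z comparison of
    correlations).  Includes a seeded synthetic-movie generator with a
    biphasic response kernel, glomerulus-like spatial patterns structured by
    carbon chain length and functional group, photobleaching, illumination
    jitter and pixel noise, so that every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    mvtnorm,
    png,
    readxl,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    ade4,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
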