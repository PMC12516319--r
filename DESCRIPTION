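Package: gastromorph
Title: Morphometry, Axial Expression Profiling and Motility Statistics
    for Gastruloid Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative image analysis for elongating stem-cell
    organoids (gastruloids). Segments single-organoid silhouettes from
    brightfield or DAPI images, measures medial-axis length,
    straightness, elongation index and aspect ratio, extracts 100-bin
    anteroposterior intensity profiles with per-experiment decile
    normalization and half-maximum boundary calling, scores BRA/SOX2
    pole formation with bootstrap uncertainty, counts mitotic nuclei by
    maximum-entropy thresholding and watershed splitting, and computes
    single-cell track statistics (mean speed, confinement ratio,
    directional change rate, mean squared displacement with diffusion
    coefficient and exponent). A synthetic-scene generator provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    EBImage,
    igraph,
    mgcv,
    pracma,
    withr,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
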