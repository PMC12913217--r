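Package: nucleoquant
Title: Quantification of Nucleolar Morphometry, PolyQ Aggregation and
    Polysome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image- and trace-based quantification pipelines for cellular
    proteostasis readouts. Segments nuclei and nucleoli in multi-channel
    fluorescence micrographs and computes per-nucleus morphometry (nucleolus
    counts, nucleolar/nuclear area ratios, marker presence ratios, integrated
    intensities, with a nascent-RNA/FUrd variant); defines cells around
    nuclear seeds and scores polyglutamine-EGFP aggregation by gray-level
    co-occurrence texture contrast, Laplacian-of-Gaussian focus counting and
    an S0/S1/S2 classification; normalizes sucrose-gradient OD260 polysome
    profiles at the 60S/80S valley and reports polysome/monosome ratios. A
    synthetic-scene and synthetic-trace generator produces ground-truthed
    inputs so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
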