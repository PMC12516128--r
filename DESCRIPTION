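Package: epinav
Title: Quantification of Macrophage Morphology, Motility and MTOC-Led
    Navigation in Epidermal Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the behavior of tissue-resident
    macrophages (Langerhans cells) in calibrated multi-channel 2D
    time-lapse microscopy of the epidermis. Implements cell segmentation
    and skeleton-based dendrite morphometry, Sholl profiling,
    linear-assignment particle tracking with motility metrics
    (total distance, displacement, meandering index), front-rear reporter
    polarity by mask bisection, wound-margin region-of-interest
    quantification, scoring of MTOC-led navigation around cellular
    obstacles, and classification of debris-engulfment modality. A
    seeded synthetic-scene generator produces ground-truth-annotated
    image stacks emulating steady-state surveillance, laser-ablation
    debris engulfment and scratch-wound migration assays, including
    microtubule-drug condition presets, so every stage of the pipeline
    can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    EBImage,
    igraph,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
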