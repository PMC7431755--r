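Package: hccapa
Title: High-Content Chloroalkane Penetration Assay Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the high-content chloroalkane penetration
    assay (HC CAPA): organelle-resolved, per-cell quantification of cytosolic
    delivery (CP50) and cytotoxicity from multiwell fluorescence images.
    Includes a synthetic-microscopy plate generator that emulates the assay
    (HaloTag-GFP expression, Hill-type HaloTag blocking, off-target reporter
    puncta, damaged cells, transient-transfection mixtures), watershed-based
    nucleus/cell-body/organelle segmentation, per-cell feature extraction with
    damaged-cell and transfection-gate quality control, per-cell GFP-reporter
    regression, four-parameter logistic dose-response fitting, toxicity
    curves, and paired mask comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    scales,
    optparse
Config/testthat/edition: 3
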