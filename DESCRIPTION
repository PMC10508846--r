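Package: chondroquant
Title: Quantification of Chondrocyte Viability, Calcium Signaling and
    Immunofluorescence in Cartilage Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image and trace quantification pipelines for articular-cartilage
    chondrocyte experiments: impact-induced cell-death quantification from
    paired pre/post live-dead confocal Z-stacks (maximum-intensity projection,
    Otsu thresholding, distance-transform watershed segmentation,
    translation-based region-of-interest registration), ratiometric calcium
    trace analysis with a baseline-referenced responsive-cell criterion and
    agonist-evoked delta-calcium summaries, and per-cell immunofluorescence
    integrated-density quantification with circularity-based ROI selection
    and joint-level scores. A synthetic micrograph and trace generator with
    exact ground truth makes every stage testable end to end, and a thin
    experiment driver adds the standard paired/unpaired t-test and ANOVA
    group comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
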