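Package: delamina
Title: Delamination Strength and Medial Composition Analysis for Aortic Peel
    Tests and Stained Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for studying aortic dissection in rodent
    models. Extracts delamination strength from T-peel force-time traces by
    width normalization and sigmoid-plateau fitting, quantifies medial tissue
    composition (elastin, collagen, smooth muscle) from Elastica-Masson and
    Azan stained sections by nearest-centroid RGB classification, isolates
    interlaminar elastin fibers by green-channel thresholding, binary opening
    and particle circularity filtering, and links the mechanical and
    histological measurements with two-way ANOVA, Tukey-Kramer multiple
    comparisons and Pearson correlation tests. Includes a synthetic-data
    generator producing peel traces and layered histology-like images with
    known ground truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
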