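Package: radfoci
Title: Automated Quantification of DNA Damage Foci for Ex Vivo
    Radiosensitivity Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of DAPI / 53BP1 confocal Z-stacks of
    irradiated tumor tissue: focal-plane selection and three-slice maximum
    projection, semantic segmentation of nuclei and DNA damage foci with a
    compact U-net (trained with a soft Jaccard loss), watershed-based
    separation of clustered nuclei with border and minimum-area filtering,
    per-nucleus foci counting and foci-per-nuclear-volume quantification,
    segmentation evaluation (pixel Dice/IoU and object-level Dice with
    centroid matching), and condition comparison statistics (Kruskal-Wallis
    with Dunn's post hoc, relative standard deviation). Includes a
    calibrated synthetic tissue-image generator with exact ground truth so
    the whole pipeline is trainable and testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
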