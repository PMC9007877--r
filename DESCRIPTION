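Package: nucmorph
Title: Nuclear Morphometry and Stage Classification for Histology Patches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative histomorphometric analysis of segmented cancer
    nuclei in histology image patches. Computes per-nucleus shape, Haralick
    co-occurrence texture, Delaunay and cell-cluster-graph architecture,
    orientation-disorder and cellular-diversity feature families; ranks
    features by the Wilcoxon rank-sum test; classifies tumor stage with a
    random forest and per-patient patch-majority voting; and provides
    Kaplan-Meier, log-rank, concordance-index and Cox survival analysis
    together with hierarchical clustering and 2-D embedding of patient
    feature profiles. Includes a synthetic nuclei-cohort generator that
    emulates stage-dependent nuclear morphology so the whole pipeline is
    testable without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    randomForest,
    survival,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    uwot,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
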