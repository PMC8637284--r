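Package: exermet
Title: Paired Exercise Metabolomics and Exercise Oximetry for
    Lower-Extremity Artery Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired (rest versus post-exercise)
    targeted metabolomics coupled with treadmill transcutaneous oximetry
    in lower-extremity artery disease. Implements quantitation-range
    quality control for the AbsoluteIDQ p180 metabolite panel, DROP
    (decrease from rest of oxygen pressure) indices and an
    ischemia-severity score from multi-probe TcPO2 recordings, multilevel
    (paired) PCA and PLS-DA with NIPALS, an exhaustive-combination
    ensemble validation scheme with median-AUROC model selection,
    VIP/loading-based discriminant-metabolite selection, Pearson
    correlation of exercise-induced metabolite changes with clinical
    severity indices, and a synthetic-cohort generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
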