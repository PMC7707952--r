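Package: cytodx
Title: Computer-Aided Thyroid Cytodiagnosis from Nuclear Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative evaluation of thyroid fine-needle aspiration
    cytology. Extracts 23 geometric and densitometric features from
    manually delineated nucleus boundaries on digitized liquid-based
    cytology images, classifies individual nuclei as benign or malignant
    with a three-layer radial basis function network, aggregates nucleus
    calls into a per-patient diagnosis through count- and
    percentage-threshold classifiers with a balanced
    sensitivity/specificity threshold sweep, and reports the full panel
    of diagnostic performance indices with two-proportion z-tests and
    ROC/AUC comparisons. Includes a seeded synthetic-cohort generator
    and an analytic nucleus renderer so the complete pipeline can be
    exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    pROC,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mgcv
Config/testthat/edition: 3
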