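Package: progwalk
Title: Prognostic Gene Selection from Random-Walk Embeddings of
    Outcome-Specific Correlation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns distributed gene representations by training a shallow
    bag-of-genes classifier on random walks drawn from prognosis-group
    specific correlation networks, then scores genes by embedding distance
    and differential expression, selects a biomarker panel per outcome
    group, and validates panels by cross-validated random-forest outcome
    prediction. Includes a synthetic-cohort simulator with planted
    co-expression modules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    randomForest,
    pROC,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
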