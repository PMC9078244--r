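Package: csarpipe
Title: Classification Structure-Activity Relationship Pipeline for
    Anti-Sickling Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native workflow for classification
    structure-activity relationship (CSAR) modeling of anti-sickling
    agents: solubility-ratio labeling, compound standardization and
    deduplication, substructure-count fingerprints and Lipinski
    properties via OpenBabel, dataset modelability (MODI), balanced
    undersampling (random and Kennard-Stone), stratified resampling and
    repeated cross-validation, random-forest models with Gini-importance
    ranking of privileged substructures, class-comparison statistics,
    PCA bounding-box applicability domain analysis, and a synthetic-data
    generator with property-matched decoys so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
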