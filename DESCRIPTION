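Package: sdmelect
Title: Election Ensembles for Presence-Background Species Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A presence-background species distribution modelling pipeline
    built around ensemble elections. Occurrence tables are deduplicated,
    background points sampled, and five algorithm families (neural network,
    gradient boosting, penalized maximum-entropy logistic regression, random
    forest, support vector machine) are fitted under k-fold cross-validation
    on normalized covariate raster stacks. Continuous suitability maps are
    binarized at the sensitivity-plus-specificity-optimal threshold and
    combined by per-algorithm mean, majority-vote, and unanimous-decision
    ensembles, plus collective elections pooling every fold model. Binary
    predictions are validated by confusion matrix against a dispersal-buffer
    range mask. A virtual-species simulator generates spatially
    autocorrelated covariate landscapes, a known true suitability field, and
    presence/background samples so the whole pipeline is testable without
    external climate or occurrence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    geosphere,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
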