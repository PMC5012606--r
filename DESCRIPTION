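Package: affectmvpa
Title: Trial-Level Decoding of Valence and Arousal from fMRI Activity Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying the core-affect dimensions of
    valence and arousal from distributed fMRI voxel activity patterns evoked
    by naturalistic audiovisual stimuli. Provides low-level stimulus feature
    extraction (HSV colour, lagged motion energy, stereo amplitude and
    spectral frequency) with summary-statistics ANOVA balance checks and
    block-wise principal-component nuisance scores; INDSCAL individual-
    differences scaling of behavioural ratings; percent-signal-change trial
    pattern extraction with nuisance regression and localizer mask algebra;
    L2-penalized logistic-regression decoding under within-participant,
    cross-exemplar and cross-participant cross-validation with permutation
    significance; box searchlight mapping with random-effects group maps and
    max-cluster-size permutation inference; and confirmatory cluster analyses
    (stability-based voxel selection, STATIS compromise spaces, point-biserial
    design correlations). A synthetic-data module generates stimuli, ratings
    and multi-participant BOLD datasets with known ground truth so every stage
    is testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
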