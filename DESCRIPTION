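Package: subcortstage
Title: Subcortical Geometry Features and Staged Classification of Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts thalamus-referenced geometric features (normalized volumes,
    Euclidean and cosine centroid distances) from labeled subcortical segmentation
    volumes, runs the associated group-comparison statistical battery (one-way
    ANOVA, Welch pairwise t-tests, chi-squared for sex, Benjamini-Hochberg FDR),
    and fits a staged three-task binary classification workflow (random-forest
    feature voting, grid-searched logistic regression / random forest / support
    vector classifiers, probability-summing ensemble) for distinguishing healthy
    control, prodromal, and Parkinson's disease cohorts. Includes a synthetic
    cohort generator (labeled 3D phantoms or parametric feature tables) with
    known ground truth, and a minimal Pawlak-style rough-set rule classifier for
    interpretable validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    glmnet,
    randomForest,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
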