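Package: rgbomics
Title: RGB Three-Channel Ultrasomics for Color Shear-Wave Elastography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomics analysis of color-coded shear-wave elastography (SWE)
    images comparing two color-image preprocessing strategies: direct luminance
    conversion (0.2126R + 0.7152G + 0.0722B) and lossless decomposition into the
    three R, G, B single-channel images. Provides a synthetic elastogram cohort
    generator (including a metameric mode in which lesion classes are separable
    in RGB but not after luminance conversion), first-order/GLCM/GLRLM feature
    extraction with LoG and stationary-wavelet filter banks, SMOTE class
    rebalancing, LASSO feature selection, four risk-score classifiers (random
    forest, SVM, AdaBoost, logistic regression), and a model-comparison suite:
    ROC/AUC with DeLong variance and paired test, confusion metrics with exact
    binomial intervals, two-category net reclassification index, Brier score,
    calibration curves, and decision-curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    randomForest,
    e1071,
    rpart,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    mgcv
Config/testthat/edition: 3
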