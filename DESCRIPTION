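Package: saffronvision
Title: Machine-Vision Grading of Bulk Saffron from Color and Texture Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nondestructive grading of bulk saffron images into the
    Iranian commercial classes Pushal, Negin and Sargol. Implements the full
    analysis pipeline: morphological foreground segmentation of saffron
    filaments on a dark background, extraction of 21 color features (18
    color-space channel means plus hue-window composition percentages) and 99
    texture features (gray-level co-occurrence statistics, local entropy and
    standard-deviation filters, local binary patterns, histogram statistics),
    a 22-classifier benchmark under repeated stratified k-fold
    cross-validation, and statistical comparison of classifiers by one-way
    ANOVA with Duncan's multiple range test. A synthetic scene generator
    renders labeled bulk-saffron images with exact ground-truth composition
    so every stage is testable without a reference image collection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    igraph,
    e1071,
    rpart,
    randomForest,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    MASS,
    class,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
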