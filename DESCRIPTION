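Package: geomexpr
Title: Geometric Landmark Features and Feature Selection for Facial
    Expression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts 89 normalized 2D/3D geometric features (inter-landmark
    distances and three-point angles) from 22 anatomical facial landmarks and
    classifies the six basic expressions (anger, disgust, fear, happiness,
    sadness, surprise). Implements feature-subset selection by PCA variance
    thresholding and by a wrapper genetic algorithm whose fitness is the
    cross-validated accuracy of a cubic-kernel support vector machine, SMOTE
    class balancing, polynomial-kernel one-vs-one SVMs, nearest-neighbour and
    random-subspace ensemble classifiers, repeated stratified cross-validation
    reporting, and a synthetic 22-landmark face generator so the full pipeline
    runs without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
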