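Package: symcomp
Title: Mirror Symmetry, Image Compressibility and Perceived Visual Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling perceived visual complexity of abstract
    black-and-white patterns. Provides a simulated-annealing generator for
    triangle-grid patterns with controlled mirror symmetry (including locally
    broken, just-not-symmetric variants), a weighted four-axis mirror-symmetry
    measure with non-linear (power, exponential and threshold-stretch)
    transforms, a battery of 24 image predictors combining file-compression
    ratios (GIF, PNG, TIFF-LZW, JPEG) with edge-operator statistics (phase
    congruency, Canny, perimeter, local RMS contrast) and structural measures
    (balance, centre-of-mass deviation, homogeneity), and a model-fitting
    harness: exhaustive best-subset linear regression, cross-validated random
    forests, per-participant models and random-slope mixed-effects
    comparisons. A seeded rating simulator with a two-factor
    (quantitative + structural) generative model makes the whole pipeline
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    jpeg,
    randomForest,
    lme4,
    EBImage,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
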