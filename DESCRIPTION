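Package: npOptim
Title: Optimization of Neuropsychological Test Batteries for
    Dementia-Severity Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to identify minimal sets of neuropsychological measures
    that discriminate clinical dementia rating (CDR) groups. Implements two
    feature-reduction strategies (a Fisher's Discriminant Ratio filter and an
    expert-curated catalog followed by single-feature classification-accuracy
    ranking), support vector machine classification with linear, quadratic,
    Gaussian RBF and sigmoid (multilayer perceptron) kernels, class-balanced
    nested 10-fold cross-validation with exhaustive feature-subset
    optimization in the inner loop, imbalance-aware performance metrics
    (geometric mean of the true rates and dominance), and frequency-based
    ranking of best-predictor measures across resampling iterations. Ships a
    curated 131-measure catalog spanning twelve standard instruments (MMSE,
    clock drawing, logical memory, AVLT, digit span, category fluency, trail
    making, Boston naming, ANART, ADAS-Cog, GDS, FAQ) and a synthetic cohort
    generator with planted group effects and within-instrument correlation so
    the full pipeline is testable without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, e1071, jsonlite, yaml
Suggests: testthat (>= 3.0.0), kernlab, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
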