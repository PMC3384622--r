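Package: plaquepc
Title: Differential Profiles and Local Causal Discovery for Plaque
    Macrophage Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for two-color reference-design microarray
    studies of atherosclerotic plaque regression. Combines fluoro-reverse
    duplicate arrays, re-ratios samples against their batch pool, builds a
    differential profile through a conjunctive filter cascade (two-group
    ANOVA criteria, a variance-moderated error-model filter, and a fold
    change threshold) with a permutation-based false-positive estimate,
    tests up- and down-regulated clusters for gene-set over-representation,
    discovers the local causal neighborhood of the regression label with
    Semi-Interleaved HITON-PC using Fisher's Z conditional-independence
    tests, and evaluates multivariate molecular signatures with linear SVM
    classifiers under leave-one-out cross-validation and permutation-based
    significance. Includes a synthetic-data generator that emulates the
    three-group, two-batch, dye-swap design with planted effects and a
    known linear-Gaussian causal neighborhood for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
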