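Package: damu
Title: Diagnostic Accuracy Measures Under Measurement Uncertainty
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes, optimizes, differentiates and compares diagnostic
    accuracy measures and expected-loss risk for binary tests on a normally
    distributed measurand, as explicit functions of the standard measurement
    uncertainty of the test. Implements the binormal model of sensitivity and
    specificity against a diagnostic threshold, their mutual inverses, ROC and
    predictive ROC (PROC) curves with closed-form AUC, predictive values,
    likelihood ratios, diagnostic odds ratio, Youden's index, Euclidean
    distance to the perfect-accuracy point, concordance probability and
    prevalence-weighted expected-loss risk. Provides analytic partial
    derivatives of every measure with respect to measurement uncertainty,
    two-test comparison (difference, relative difference, ratio),
    deterministic optimal-threshold solvers for the four objective and loss
    functions, a YAML/JSON configuration layer and a command-line interface.
    Ships normalized oral glucose tolerance test (OGTT) case-study parameters
    as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
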