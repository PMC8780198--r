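Package: proxiscale
Title: Machine-Learning Scaling of Proximal Weakness and Multi-Rater
    Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for sensor-based grading of proximal limb weakness on a
    modified Medical Research Council (MRC) ordinal scale and for comparing
    the reliability of manual and machine-learning grading across raters.
    Includes a synthetic drift-test cohort generator (3-axis accelerometer
    traces with grade-dependent drift and oscillation, plus rater confusion
    noise), tilt-angle feature extraction (MeanDrift, MaxDrift, SumOsc),
    boosting-factor class balancing with SMOTE interpolation, ordinal
    misclassification cost matrices, cost-sensitive ensemble classifiers
    (bagging, AdaBoost, RUSBoost over CART trees) with minimum-expected-cost
    prediction and Gaussian-process model selection, and from-scratch
    agreement statistics: percent agreement, Bland-Altman limits of
    agreement, ICC(2,k), Krippendorff's alpha, and Fleiss' kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
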