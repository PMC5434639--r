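Package: fmgrasp
Title: Temporal Feature Extraction and Wrapper Evaluation for Force
    Myography Grasp Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-class grasp detection problem (grasp versus
    no grasp) from multichannel force myography (FMG) recordings. Implements
    sliding-window temporal feature extraction (mean absolute value, root
    mean squared, linear fit, parabolic fit, and Yule-Walker autoregressive
    coefficients) over symmetrically centered overlapping windows, thumb
    sensor based ground-truth labeling, and a wrapper feature evaluation
    framework with round-wise three-fold cross-validation of an RBF-kernel
    support vector machine scored by ROC AUC. Includes a synthetic cohort
    generator that emulates multi-stage grasp force profiles, movement
    artifacts, baseline drift, and 10-bit quantization, so the full pipeline
    is testable without access to recorded data.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
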