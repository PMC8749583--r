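Package: emgkit
Title: Surface-EMG Hand and Finger Gesture Recognition Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for classifying hand and finger gestures
    from three-channel surface electromyography (EMG). Includes a
    protocol-faithful synthetic EMG generator (band-limited stochastic
    carriers, trapezoidal activation envelopes, 60 Hz line interference,
    inter-subject variability), Butterworth bandpass/bandstop
    preprocessing evaluated as second-order sections, overlapping
    sliding-window segmentation with amplitude-threshold activation
    annotation, the six classical time-domain features (RMS, VAR, MAV,
    SSC, ZC, WL), class balancing and train/test splitting, grid-searched
    stratified cross-validation over four classifier families (multilayer
    perceptron, SVM, random forest, multinomial logistic regression), and
    heteroscedasticity-robust method comparison (Levene, Welch ANOVA,
    Games-Howell, variance F-tests with FDR correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    ranger,
    glmnet,
    nnet,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
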