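Package: fogsentry
Title: Freezing-of-Gait Prediction from Plantar-Pressure Center-of-Pressure Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to predict and detect freezing-of-gait (FOG) episodes in
    Parkinson's disease from two-foot plantar-pressure recordings. Implements
    center-of-pressure (COP) extraction with a 5 percent ground-reaction-force
    validity rule, overlapping 1 s window features (AP COP reversals, dominant
    FFT frequency of COP velocity, wavelet approximation-coefficient power), a
    from-scratch RUSBoost ensemble of shallow decision trees for the imbalanced
    target class, episode-level evaluation via model trigger decisions (MTDs)
    with target zones, no-cue suppression and identification delays, and
    leave-one-freezer-out cross-validation. A parameterized two-foot gait
    simulator generates annotated walking, turning, standing, pre-FOG and FOG
    (trembling and akinetic) recordings with ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
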