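Package: synspace
Title: Synergy-Space Recurrent Decoding of Forearm Motion from Shoulder Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating forearm joint angles (elbow flexion-extension,
    forearm pronation-supination) from residual shoulder kinematics via spatial
    kinematic synergies. Provides PCA-based synergy extraction with explained
    variance component selection, a windowed stacked-LSTM sequence regressor
    trained on synergy activation signals (or directly on forearm angles),
    reconstruction of forearm trajectories through the synergy loading matrix,
    personalized and cross-subject transfer evaluation, one-way ANOVA from
    group summaries and Tukey HSD post hoc tests based on the studentized
    range distribution, and a synthetic reaching-motion generator that emulates
    a multi-target horizontal reaching protocol for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
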