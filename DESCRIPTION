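Package: reciprocalEEG
Title: Reciprocal EEG Lead Fields with a Charge-Based Boundary-Element Forward Solver
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of EEG lead-field matrices by Helmholtz reciprocity
    using a charge-based boundary-element forward solver on nested triangulated
    head models. Includes synthetic icosphere head models with electrode
    imprinting, analytic multilayer-sphere oracles (Legendre series), PCA
    correction of the reference-electrode bias in reciprocal basis functions,
    signal preprocessing for steady-state visual evoked potentials (FIR
    bandpass, Welch/Savitzky-Golay alpha-peak estimation, epoching, common
    average reference, noise covariance), a depth-weighted minimum-norm inverse
    operator with dSPM normalization, and a seeded photic-stimulation simulator
    for end-to-end source-localization validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
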