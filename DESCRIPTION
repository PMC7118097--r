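Package: wristnms
Title: Neuro-Musculoskeletal Mapping of Motor-Unit Discharges to Wrist Kinematics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for model-based myoelectric interfacing at the wrist.
    Decomposed motor-unit spike trains are converted to per-window discharge
    counts, mapped to muscle excitations by robust per-unit linear regression
    with a median ensemble and neural-network fallback, and fed to a
    self-contained Hill-type wrist model whose open-loop forward dynamics
    yields joint kinematics in three degrees of freedom. Includes a
    computed-muscle-control style calibration (PD kinematic tracking plus
    static optimization with an antagonist-zero constraint), classical
    time-domain surface-EMG regression baselines, a synthetic neuromuscular
    data generator for end-to-end testing, and cross-validated evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
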