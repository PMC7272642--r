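Package: megspect
Title: Source-Level MEG Spectral Biomarkers for Eyes-Closed/Eyes-Open Resting Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for resting-state
    magnetoencephalography (MEG) spectral biomarkers of early-stage
    Alzheimer's disease. Generates synthetic multichannel MEG cohorts from a
    spherical-conductor forward model with parcellated cortical sources;
    preprocesses recordings (amplitude-threshold artifact rejection, 2-s
    epoching, zero-phase band-pass filtering into theta1/theta2/alpha1/
    alpha2/beta bands); reconstructs cortical activity with a
    Tikhonov-regularized weighted minimum-norm inverse; extracts regional
    absolute power, whole-cerebral-normalized (WCN) z-scores and
    eyes-closed minus eyes-open reactivity features; and runs
    Bonferroni-corrected group comparisons plus polynomial-kernel support
    vector machine classification with stratified cross-validation and ROC
    analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
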