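Package: nirsBFN
Title: Brain Functional Network Fingerprinting for Multi-Channel fNIRS
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates subject-specific brain functional network (BFN)
    fingerprints from multi-channel functional near-infrared spectroscopy
    (fNIRS) concentration-change signals and evaluates their use as a
    biometric. Provides a block-design cohort simulator (subject-specific
    latent connectivity, canonical hemodynamic responses, systemic
    physiological nuisance), Butterworth band-pass filtering with
    global-signal baseline correction, trial segmentation into task and
    rest epochs, Pearson-correlation network estimation with class
    averaging, and nearest-neighbour individual identification across
    task states and across the oxy-/deoxy-hemoglobin views, including
    full cross-task and cross-view accuracy matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
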