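Package: anklemsk
Title: EMG-Driven Musculoskeletal Estimation of Ankle Moment and Stiffness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates ankle joint moment and rotational stiffness during the
    stance phase of walking from surface electromyography of four ankle
    muscles (tibialis anterior, soleus, and the two gastrocnemii) with an
    EMG-driven musculoskeletal model. Provides zero-phase Butterworth EMG
    envelope processing, recursive neural-activation dynamics with
    electromechanical delay, Hill-type muscle-tendon dynamics with an
    elastic-tendon equilibrium solver, polynomial muscle-tendon-unit
    geometry surrogates, bounded Nelder-Mead model calibration against an
    inverse-dynamics moment, curve-level comparison of stance-phase
    waveforms across walking-surface conditions via one-way
    repeated-measures ANOVA fields with permutation (suprathreshold
    cluster) inference, and a seeded synthetic gait-trial generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    lhs,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
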