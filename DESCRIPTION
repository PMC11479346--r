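Package: vimsdetect
Title: Multimodal Physiological Detection of Visually Induced Motion Sickness
Version: 0.1.0
Authors@R:
    person("vimsdetect", "developers", email = "vimsdetect@example.org",
           role = c("aut", "cre"))
Description: Tools to detect visually induced motion sickness (VIMS) from
    low-burden multimodal physiological recordings (ECG, respiration
    accelerometry, electrodermal activity, horizontal EOG and four-channel
    parieto-occipital EEG). The package extracts 23 physiological features on
    a sliding 30-second window at 1-second resolution (heart-rate and
    heart-rate-variability spectral indices, respiratory period, tonic and
    phasic electrodermal components, saccade dynamics, EEG band-power ratios
    and peak frequencies, and the lambda response of the eye-fixation-related
    potential), standardizes them as ratios to a per-session baseline,
    labels each second from stepwise subjective sickness reports, and trains
    a gradient-boosted decision-tree classifier evaluated by
    leave-one-participant-out cross-validation. A seeded synthetic-signal
    generator with ground truth makes the full pipeline testable without
    access to human recordings. Includes normalized-time trend analysis of
    features against sickness level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
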