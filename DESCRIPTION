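Package: msalpha
Title: Microsaccade-Locked Lateralisation of EEG Alpha Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how spontaneous microsaccades relate to transient
    lateralisation of posterior EEG alpha (8-12 Hz) power. Implements
    velocity-based microsaccade detection from binocular gaze recordings
    (binocular averaging, blink padding, median-velocity thresholding with a
    refractory period, magnitude and displacement filters, start/return
    classification), saccade-locked EEG epoching, short-time Fourier
    time-frequency decomposition, contralateral-versus-ipsilateral power
    contrasts, baselined log-power change, inter-trial phase coherence, and
    two-sided cluster-based sign-flip permutation inference over
    time-frequency maps. A synthetic-data generator produces gaze and EEG
    recordings with known ground truth (injected microsaccades and a
    lateralised alpha-burst effect) so the whole pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
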