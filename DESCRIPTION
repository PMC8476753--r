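Package: prompkl
Title: Probabilistic Movement Primitives and Symmetric Kullback-Leibler
    Divergence for Repetitive Motion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Probabilistic Movement Primitives (ProMPs) to sets of
    segmented, phase-normalized multi-channel acceleration strokes recorded
    during repetitive finger-tapping tasks, and quantifies differences between
    experimental conditions with a closed-form symmetric Kullback-Leibler
    divergence between the induced trajectory distributions. Includes tap
    detection and stroke segmentation for pad-instrumented recordings,
    phase-grid time normalization, reconstruction-loss based selection of the
    number of basis functions, three-sigma outlier exclusion, sliding-window
    time-localized divergence profiles, and a seeded synthetic-study generator
    emulating a multi-participant transcranial current stimulation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
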