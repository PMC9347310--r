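Package: caldrift
Title: Day-to-Day Stability of Sound-Evoked Calcium Responses in Auditory Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying day-to-day stability and drift of
    auditory cortical responses recorded with two-photon calcium imaging.
    Provides acoustic complexity metrics for stimulus sets (occupied bandwidth,
    spectral entropy, spectrotemporal modulation index), trial-level dF/F
    response extraction with locomotion exclusion, bootstrap responsiveness and
    cross-day change shuffle tests, response-profile drift metrics, day-by-
    stimulus interaction ANOVA with omega-squared effect sizes, cross-session
    neuron matching by image registration and structural similarity, the
    group-level inferential statistics used for such comparisons, and a
    synthetic-data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
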