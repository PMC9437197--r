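Package: cortone
Title: Tonotopic Selectivity from Cortical Onset Responses and Masked Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring tonotopic (frequency) selectivity of hearing
    with matched electrophysiological and behavioural paradigms, in humans and
    in cats. Synthesizes the band-limited, pink and notched-noise maskers and
    ramped tone probes used in simultaneous-masking experiments; extracts
    cortical onset response (COR) amplitudes from triggered scalp recordings
    with species-specific presets (P1-N1 in cat, P2-N1 in human); scores
    hold-release detection sessions with weighted false-alarm catch-trial
    logic, d-prime and unbiased proportion correct P(c)max; simulates and
    scores 2-down 1-up adaptive staircases; fits symmetric roex(p) auditory
    filters to notched-noise thresholds with subject-resampling bootstrap
    ERBs; and converts COR masking into equivalent psychophysical threshold
    shifts via level-growth slopes. A synthetic-data layer generates scalp
    recordings, behavioural sessions and notched-noise thresholds with known
    ground truth so that every analysis stage has a closed recovery loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
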