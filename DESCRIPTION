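Package: ecogclick
Title: Click Decoding for Electrocorticographic Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, training and evaluation of a click-based
    electrocorticographic (ECoG) brain-computer interface. Provides a seeded
    synthetic ECoG generator with ground-truth event schedules, high-gamma
    (110-170 Hz) spectral feature extraction against a resting calibration
    baseline, a small LSTM rest-vs-grasp sequence classifier with contiguous
    balanced cross-validation, a packetized real-time engine with a voting
    window and click lockout, switch-scanning communication-board and speller
    simulations with a modelled user, event-detection performance metrics
    (sensitivity, true/false positive frequencies, latencies, correct
    characters and words per minute), and integrated-gradients channel
    saliency with channel-subset ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
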