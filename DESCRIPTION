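Package: mazesim
Title: Headless Engine for Zone-Triggered Rodent Maze Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A hardware-free re-implementation of a zone-based behavioral
    experiment platform for spatial-cognition research. Provides circular-zone
    geometry with entry hysteresis on a 32-position perimeter platform, a
    session state machine for zone-triggered reward sequencing (ordered or
    randomized rewarded-zone lists, dwell-delay gating, manual advance),
    binary TTL encoding of maze events onto virtual digital-output banks,
    stimulation pulse-train generation (frequency, duration, duty cycle,
    unipolar/bipolar, edge triggering), a blob-tracking video pipeline with
    sequential-LED spatial auto-calibration, a synthetic animal/camera
    simulator with presets for the platform's published task configurations,
    and post-session analyses (trial segmentation, reward-aligned velocity
    profiles, lost-tracking exclusion, performance criterion rules).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
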