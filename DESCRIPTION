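Package: seatkit
Type: Package
Title: Sedentary-Behaviour Prompt and Wear-Time Analytics for Posture-Sensor Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing epoch-level posture and activity-count data
    from waist-worn inclinometers and hip-worn accelerometers used in
    sedentary-behaviour feasibility trials: detection of haptic vibration
    prompts from consecutive sedentary time, classification of post-prompt
    behavioural responses and their latency and magnitude, accelerometer
    non-wear detection and valid-day filtering, device adherence and
    overnight charging-compliance scoring, CONSORT-style trial-flow metrics
    with small-cell test selection, and a seeded synthetic-cohort generator
    that emits posture and count series together with a ground-truth event
    log for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
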