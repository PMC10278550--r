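Package: pupilcopy
Title: Pupillometric Analysis of Visual Working Memory Encoding in Copy Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the depth of visual working memory encoding
    from combined gaze and pupil recordings in self-paced copy tasks.
    Raw 1000-Hz eye-tracking streams are segmented into sampling events
    (left-screen visits that survive an imposed delay) using a 100-ms
    hysteresis rule; per-event dwell times, build durations, baseline
    pupil size, and pupil orienting-response amplitudes are extracted;
    and linear mixed-effects models with by-participant random condition
    slopes relate these ocular metrics to encoding depth and to
    continuous-report precision. A synthetic-data generator with planted
    effects makes every stage of the pipeline verifiable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
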