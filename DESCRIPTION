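Package: repstream
Title: Design, Simulation, and Scoring of Repetition Detection in RSVP
    Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying repetition detection and memory in rapid
    serial visual presentation (RSVP) streams.  Builds session designs in
    which a target image repeats six times with regular or irregular
    distractor spacing, simulates a synthetic observer (button presses with
    a shifted-lognormal reaction-time law, Poisson false alarms, and
    four-alternative forced-choice memory responses with confidence
    ratings), scores detection with a one-and-only-one-press response
    window, estimates chance level by scrambling press timestamps, performs
    regular-versus-irregular contrasts and a stream-to-probe delay-split
    memory analysis, and provides the statistical layer: bias-corrected and
    accelerated (BCa) bootstrap confidence intervals, one-way ANOVA with
    Tukey-Kramer post-hoc tests, and JZS default-prior Bayes-factor t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
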