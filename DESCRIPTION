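Package: improv
Title: Quantitative Behavioral Analysis of Keyboard Improvisation from MIDI Event Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An event-driven tracker and metric suite for piano-keyboard
    improvisation research. Reads Standard MIDI Files and tabular note-event
    logs, reconstructs note intervals and the timeline of simultaneously held
    keys, and computes per-session expressive-behavior parameters: playing,
    idle and start times, the concurrent-playing metric, key-use and
    black/white-key statistics, duration-weighted dynamics, octave and
    pitch-class profiles, cluster-configuration statistics, and
    crescendo/diminuendo, accelerando/ritardando and chromatic transition
    rates. Includes cohort aggregation, repeated-measures ANOVA with
    Bonferroni pairwise comparisons and partial eta squared, two-sample
    t-tests with Cohen's d, textual and tabular reporting, and a synthetic
    improvisation generator with controllable statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
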