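Package: tugtmg
Title: Timed Up-and-Go Subtask Segmentation and Tensiomyography Twitch
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Segments ultrasonic distance-over-time recordings of the
    Timed Up-and-Go (TUG) mobility test into the five subtask times
    (sit-up, walk-forward, turnaround, walk-back, sit-down), extracts
    contractile twitch parameters (maximal displacement, delay time,
    contraction time) from tensiomyography (TMG) traces, and computes
    participant-level descriptive and Spearman correlation tables with
    Bonferroni-adjusted significance flags.  Ships a synthetic-data
    generator with known ground truth and a controllable rank-correlation
    structure so the whole chain can be exercised end to end as a
    parameter-recovery experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
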