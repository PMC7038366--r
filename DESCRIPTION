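Package: canegait
Title: Stride Segmentation and Gait Features from an Instrumented Cane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cane-assisted walking recorded by a
    sensor-instrumented cane (strain gauge plus inertial measurement unit)
    and an optional shank-mounted gyroscope. Implements two stride
    segmentation algorithms - a multi-sensor matched filter (MSMF) driven by
    normalized template correlation on the strain channel, and a
    threshold-based gyroscope peak detector (GPD) - together with zero-phase
    Butterworth preprocessing, two-stream synchronization, extraction of
    eight per-stride gait features (peak anteroposterior velocities and their
    timing, swing-stance ratio, peak strain and its timing, pendulum-model
    stride length, and the MSMF-GPD initial-contact difference), one-way
    repeated-measures ANOVA with Bonferroni-corrected pairwise comparisons
    across walking conditions, and a fully parameterized synthetic-signal
    generator with per-stride ground truth for eleven walking conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
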