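Package: bridgepress
Title: Concurrent Validity Analysis of Lumbopelvic Bridging Pressure Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of four-channel air-pressure recordings
    from modified hip-bridging tasks performed supine, as used to monitor
    lumbopelvic task performance during neuroimaging. Provides a synthetic
    session generator with paired digital (28 Hz stream) and analog
    (2 mmHg gauge) readouts and known ground truth; stable-pressure
    extraction via zero-phase dual-pass Butterworth filtering, velocity
    peak and zero-crossing event detection, and delayed plateau averaging;
    task-compliance classification from expected per-channel pressure
    directions; and concurrent-validity statistics: Spearman correlations
    with Fisher-z confidence intervals, Bland-Altman agreement analysis,
    and correlation power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
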