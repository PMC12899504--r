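Package: fcdetect
Title: Foot Contact Detection from Wearable Inertial Sensor Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects initial contact and toe-off during high-dynamic sports
    movements (90-degree changes of direction, sprint decelerations) from
    wearable inertial sensors.  Implements three peak-pattern detectors on
    60 Hz IMU channels -- one driven by pelvis vertical velocity, one by the
    resultant foot acceleration, and a hybrid that gates between them on the
    foot-acceleration magnitude at initial contact -- together with the
    force-platform reference rule (50 N crossing of the vertical ground
    reaction force at 1000 Hz), agreement statistics (median offset and IQR,
    Bland-Altman limits of agreement, linear mixed-effects error models,
    Pearson error-source correlations), and a seeded synthetic-trial
    generator with planted events so the whole chain is testable without
    raw laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    lme4,
    lmerTest,
    ggplot2,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
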