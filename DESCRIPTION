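Package: cgmeval
Title: Accuracy and Reliability Evaluation of Continuous Glucose Monitoring in Intensive Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to evaluate continuous glucose monitoring (CGM) devices
    against intermittent blood-gas reference measurements in critically ill
    patients. Extracts comparative sensor/reference pairs under the usual
    calibration and data-gap exclusion rules, computes point-accuracy
    statistics (mean absolute relative difference with confidence interval,
    2013 consensus criteria, Bland-Altman bias and limits of agreement,
    Clarke error grid, a surveillance-style clinical risk surface, rank
    correlation), detects and classifies real-time display gaps, summarises
    device reliability, derives glycemic metrics (dysglycemia bands, newly
    developed events, time in range, standard deviation, glycemic lability
    index), stratifies accuracy by glucose range and variability, performs
    time-shift lag analysis, and compares glycemic control longitudinally
    and in parallel between intermittent and continuous monitoring. Includes
    a fully seeded synthetic ICU cohort generator (mean-reverting glucose
    dynamics, first-order interstitial lag, calibration-anchored sensor
    drift, data gaps, premature removals) so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
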