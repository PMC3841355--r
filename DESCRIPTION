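Package: actitrial
Title: Accelerometer Processing, Design and Outcome Analysis for a
    Web-Based Physical Activity Trial
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates raw tri-axial accelerometer recordings and two-arm
    trial cohorts with known ground truth, processes raw acceleration into
    daily activity counts and minutes of moderate-to-vigorous physical
    activity (first-order RC high-pass filtering, resultant acceleration,
    automated non-wear detection, one-minute epoch integration and MET-style
    cut-point classification, valid-day summarisation), and implements the
    design and analysis arithmetic of a waitlist-controlled randomized trial:
    eligibility screening, gender-stratified permuted-block randomization,
    two-sample power and sample-size calculation with dropout inflation,
    intention-to-treat and per-protocol effect tables with within- and
    between-group tests, and derived metabolic endpoints (BMI, waist-hip
    ratio, HOMA-IR, Friedewald LDL).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
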