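Package: cryohrv
Title: Heart Rate Variability and Rank-Based Longitudinal Analysis for
    Cold-Stimulation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete analytic chain of a whole-body
    cold-stimulation (cryostimulation) heart rate variability study:
    autoregressive spectral decomposition of RR-interval series into
    low- and high-frequency components, construction of the Autonomic
    Nervous System Index (ANSI) as a two-stage percentile-rank composite
    of RR mean, RR variance and the orthostatic change in normalized LF
    power, and nonparametric rank-based ANOVA-type inference with
    relative treatment effects for the F1-LD-F2 longitudinal factorial
    design (one whole-plot treatment factor, two within-subject factors).
    Includes a synthetic-cohort generator emulating a two-arm pre/post
    by first/last-session design, descriptive reporting, and a pipeline
    driver with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
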