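Package: stagedur
Title: Nonparametric Stage-Duration Estimation from Doubly
    Interval-Censored Visit Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the distribution of disease-stage
    durations from sparse longitudinal clinic-visit records in which both
    the onset and the end of each stage are interval-censored. Implements
    interval extraction from staged visit sequences (GDS/FAST dementia
    staging), the self-consistency (EM) nonparametric maximum likelihood
    estimator for doubly interval-censored durations, counting-method and
    product-limit cross-checks, per-stage summary reports, and a seeded
    synthetic-cohort generator with known ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
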