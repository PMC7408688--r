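Package: brainsig
Title: Brain-Colonization Expression Signatures for HER2-Positive Breast Cancer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies HER2-positive breast cancer cell lines by their
    growth after intracranial xenografting, quantified from longitudinal
    bioluminescence imaging; extracts a brain-colonization gene-expression
    signature from log2 microarray intensities using per-gene z-scores
    together with a within-rapid-growth-group consistency log fold-change
    bound and a rapid-versus-slow group log fold-change threshold; and
    screens signature genes for association with patient survival via
    Kaplan-Meier estimation, log-rank tests and restricted mean survival
    times. Includes seeded simulators for planted-signature expression
    matrices, exponential tumor-growth radiance series and right-censored
    proportional-hazards cohorts, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
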