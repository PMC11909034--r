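Package: csfmarkers
Title: Longitudinal Dual-Platform CSF Proteomics Biomarker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for treatment-response biomarker discovery in
    longitudinal cerebrospinal fluid (CSF) proteomics quantified on two
    complementary platforms (tandem mass tag isobaric labeling and label-free
    quantification). Implements sample- and detection-level quality filters, a
    generalized-log variance-stabilizing transformation, k-nearest-neighbour
    imputation, patient-effect removal with retained timepoint structure,
    empirical-Bayes moderated-t differential expression with patient-blocked
    designs, cross-platform protein overlap and abundance-rank analytics,
    per-patient regulation-direction consistency scores, change-change
    correlation screening against clinical motor scores, cutoff-based
    biomarker classification, and hypergeometric set enrichment. A synthetic
    cohort generator with known ground truth emulates the longitudinal study
    design (dropout, plex batch effects, missing-at-random values, planted
    treatment-responsive and clinically coupled proteins) so that every stage
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
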