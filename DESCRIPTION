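Package: eruptq
Title: Measurement-Based Assessment of Mandibular Third Molar Eruption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a measurement-based (non-staging) assessment of
    mandibular third molar eruption on dental panoramic radiographs. An
    eruption quotient is computed from annotated landmarks as the ratio of
    the perpendicular distances from the mesial cementoenamel junctions of
    the second and third molars to a simplified occlusal plane, making the
    score invariant to projection magnification. The package reads and
    validates landmark annotation tables, applies angulation-based
    eligibility rules, computes Spearman rank correlations between quotient
    and chronological age with 95% confidence intervals, estimates intra-
    and inter-rater reliability with Krippendorff's alpha for continuous
    ratings (interval or ratio metric, bootstrap confidence intervals), and
    provides a seeded synthetic cohort generator so the complete analysis
    pipeline can be exercised and validated without radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
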