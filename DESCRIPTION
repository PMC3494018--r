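Package: bitaxes
Title: Blood Informative Transcript Axis Scoring for Targeted Expression Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted peripheral-blood expression
    profiling on qRT-PCR (Ct) or microarray (log2 intensity) panels.
    Implements RNA-quality-conditioned supervised normalization of
    sample-by-probe matrices, scoring of blood informative transcript (BIT)
    axes as oriented first principal components of small transcript panels
    with missing-probe score imputation, variance-components analysis of the
    leading principal components against cohort factors with a
    label-permutation null, probe-level ANOVA and pairwise volcano contrasts,
    and axis-score association with covariates such as body mass index.
    Includes a latent-factor synthetic cohort generator so every stage of the
    pipeline can be exercised and calibrated without access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
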