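Package: crossqtl
Title: eQTL Mapping, Hotspot Fine-Mapping and Allele-Specific Expression
    for Two-Parent Segregant Panels
Version: 0.1.0
Authors@R:
    person("Cross", "QTL", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the genetic analysis of transcript-level
    variation in large haploid two-parent crosses (e.g. yeast segregant
    panels): variance-component heritability estimation with additive and
    pairwise-interaction kernels, forward-stepwise additive eQTL mapping with
    leave-one-chromosome-out polygenic correction and a permutation-grid
    false discovery rate, multivariate trans-eQTL hotspot localization with
    bootstrap confidence intervals, two-locus epistasis scans, and
    beta-binomial allele-specific expression tests and power analysis.
    Includes a synthetic-cross generator with a ground-truth ledger so that
    every stage of the pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
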