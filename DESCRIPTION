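Package: scith
Title: Single-Cell and Multi-Region Intratumor Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("scith", "developers", email = "scith@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying genomic intratumor heterogeneity from
    multi-region whole-exome and single-cell whole-genome sequencing.
    Implements bin-level single-cell copy-number profiling with MAPD
    quality control, hidden-Markov-model integer copy-number inference,
    dual-caller somatic mutation consensus with low-VAF rescue and
    ubiquitous/shared/private categorization, rule-based tumor/normal
    cell classification from validation assays, and PCA-based detection
    of subclonal copy-number alterations with PAM subpopulation calling.
    Includes a fully specified synthetic-data generator with known
    ground truth so every pipeline stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
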