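Package: stepminer2d
Title: Joint Dichotomization of DNA Methylation and Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies on/off thresholds for DNA methylation beta values and
    gene expression by fitting step functions that maximize a signal-to-noise
    ratio (the StepMiner family of algorithms), including a bivariate
    extension that rank-transforms a methylation-expression pair, builds a
    non-decreasing surface over rank space, and fits a four-block step
    function on a coarse grid. A one-sided hypergeometric test on the
    dichotomized quadrant counts flags CpG sites whose methylation is
    associated with silencing of their gene's expression, in a pooled
    (pan-cohort) analysis or separately per sample group. Includes the
    matching preprocessing filters, tab-delimited matrix readers and writers,
    a synthetic-cohort generator with planted association structure, and a
    command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
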