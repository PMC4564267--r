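Package: crossdeg
Title: Cross-Disease Meta-Analysis of Microarray Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Integrative meta-analysis of case/control gene expression
    microarray studies spanning several related diseases. Collapses probes
    to genes by largest interquartile range, intersects gene panels across
    platforms, filters un-expressed and un-informative genes by cross-study
    rank sums, computes empirical-Bayes moderated t-statistics per study,
    profiles disease similarity with signed log-p expression variation
    scores, detects genes shared across diseases by top-k and FDR criteria,
    combines per-study evidence with Fisher's method and the maximum-p
    method, and tests gene lists for over-representation against
    user-supplied gene sets. Ships a seeded multi-study simulator with
    planted shared disease genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
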