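Package: mplkit
Title: DNA Methylation Plasticity Analysis from Beta-Value Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies DNA methylation plasticity (MPL) from Illumina
    450k/EPIC-style beta-value matrices. Builds rounded-beta (r-beta)
    methylation profile curves on a 101-point grid, scores per-site
    plasticity with quantile ranges, standard deviation and range,
    classifies sites into methylation-, unmethylation- and nonbiased-
    tendency classes with a chi-square goodness-of-fit test, detects
    split methylation with a Duda-Hart homogeneity test plus k-medoids
    clustering and silhouette-based cluster-number selection, performs
    per-site differential methylation with the Mann-Whitney U test and
    Bonferroni/Benjamini-Hochberg correction, stratifies samples from
    combinations of split sites, and simulates beta-value matrices with
    known tendency, Hardy-Weinberg trimodal and sex-linked structure for
    offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
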