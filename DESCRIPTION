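Package: dcde
Title: Integrated Differential Co-Expression and Differential Expression
    Analysis by Chi-Square Maximization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Integrates differential expression (absolute Welch t statistic)
    and differential co-expression (Fisher z-transform correlation difference)
    for two-class gene expression data. For every focal gene, an optimal pair
    of thresholds on the two statistics is selected by maximizing the Pearson
    chi-square of the induced 2x2 contingency table, genes are partitioned
    into four high/low classes, the high-high association is tested and
    signed via the adjusted residual, and partitions are scored against
    functional gene sets through a functional-information gain statistic.
    Includes an independence-null simulation of the maximum chi-square
    statistic with a Bonferroni plus Benjamini-Hochberg adjustment cascade,
    a noncentral-t minimum sample size utility, and a synthetic two-class
    data generator with planted co-expression blocks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
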