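Package: dotgsa
Title: Gene-Set Association by Decorrelation of GWAS Summary Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-based association testing from per-SNP GWAS summary
    statistics. Implements the DOT statistic (decorrelation by orthogonal
    transformation: Z-scores are multiplied by the symmetric inverse square
    root of their correlation matrix and the squares summed, giving a central
    chi-square null with L degrees of freedom), the classical quadratic-form
    statistic TQ (VEGAS-style sum of squared Z-scores with a weighted
    chi-square mixture null evaluated by Imhof-type characteristic-function
    inversion), the Cauchy combination (ACAT), Bonferroni min-P, and the rank
    truncated product applied to decorrelated statistics. Provides the
    alternative-hypothesis theory linking regression effect sizes to
    noncentralities and to the correlation among association statistics,
    closed-form Helmert noncentralities and analytic power for
    equicorrelated linkage disequilibrium, a Monte-Carlo simulation engine
    for power and type-I error (including reference-panel LD
    misspecification), and an anchor-SNP gene-scan workflow with
    top-contributor SNP prioritization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite, knitr, rmarkdown
biocViews: StatisticalMethod, GenomeWideAssociation, SNP, GeneSetEnrichment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
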