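Package: agetrends
Title: Joint mRNA-Protein Aging Trend, Concordance and Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for joint analysis of age-related change in paired bulk
    transcriptome and proteome data from a cross-sectional cohort.
    Implements per-gene linear-trend likelihood-ratio tests (negative
    binomial generalized linear models for RNA-seq counts, random-intercept
    linear mixed models for protein abundances), rank-based inverse normal
    transformation and median-of-ratios normalization, z-score concordance
    classification of mRNA and protein trends, a transcriptome-wide
    nested-regression mediation scan, principal-component variance
    partitioning with covariate association, marker-based cell-type
    deconvolution via surrogate proportion variables, hypergeometric
    over-representation testing, and urinary-phenotype mediation. A
    synthetic cohort generator emulating a Diversity Outbred mouse kidney
    aging study design makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
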