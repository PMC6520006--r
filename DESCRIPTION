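Package: agevar
Title: Age-Related Differential Variability of Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for age-related changes in the inter-individual
    variability of gene expression in bulk transcriptome data. Implements
    quantile normalization and supervised covariate correction, per-gene
    differential expression on power-transformed age, two differential
    variability statistics (a continuous residual-rank correlation measure and
    a grouped interquartile-range statistic with a subsampling null and
    empirical p-values), pathway-level variability summaries, preranked gene
    set enrichment, and secondary association checks. A synthetic-data
    generator plants known mean and variance trends so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
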