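Package: flcscreen
Title: Cross-Dataset Expression Screen for Fetal Leydig Cell-Enriched Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a multi-dataset microarray screen
    for genes enriched in fetal Leydig cells. Provides a synthetic-data
    generator emulating sorted-fraction (Mafb+, Sox9+, Pou5f1+), whole-gonad
    and phthalate-exposure designs with planted marker genes and
    contamination; a simplified RMA normalization (background shift, quantile
    normalization, median-polish summarization); empirical-Bayes moderated
    t-statistics with Benjamini-Hochberg FDR; the seven-step candidate-gene
    filter cascade with platform carry-over; contamination and marker-recovery
    diagnostics with hypergeometric enrichment; and downstream quantification
    statistics (delta-delta Ct, one-way ANOVA with Dunnett comparisons,
    four-parameter logistic standard curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    multcomp,
    mvtnorm
Config/testthat/edition: 3
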