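Package: cointf
Title: Transcription Factor Discovery by Co-Inertia Analysis of Expression
    and Promoter Motif Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers transcription factors associated with an experimental
    contrast (for example, acquired drug resistance in cell-line sublines)
    by coupling a gene-by-sample expression matrix with gene-by-motif
    promoter binding-site frequency tables. Both tables are ordinated by
    non-symmetric correspondence analysis and coupled by co-inertia
    analysis, unsupervised for exploration and constrained by between-group
    analysis for supervised contrasts; motif rankings obtained at several
    position-specific scoring-matrix thresholds are aggregated with the
    rank-product statistic and reconciled across contrasts into a consensus
    list. Moderated (empirical-Bayes) differential expression with
    Benjamini-Hochberg control supplies the companion gene lists, and a
    clinical module provides immunohistochemistry score aggregation,
    contingency and correlation tests, and Kaplan-Meier/log-rank survival
    comparisons for validating a candidate factor in patient cohorts. A
    seeded synthetic-data generator with planted motif activity makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
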