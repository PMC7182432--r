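Package: scgps
Title: Single-Cell Gene-Set Percentile Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-cell expression enrichment scoring for droplet scRNA-seq.
    Implements the single-cell Geneset Percentile Score (scGPS): for every
    gene, cells are percent-ranked on log-normalized expression with ties
    assigned the lowest rank and ranks rescaled to [0,1]; a cell's score for
    a gene module is the mean percent rank over the module's genes, so a
    score of p means the module's mean expression sits at the p-th
    percentile for that cell. Ships the surrounding machinery the score is
    used with: 10x-style Matrix Market ingestion, GMT gene-set parsing,
    library-size log-normalization, cluster summary statistics (percent
    expressing, z-scored means), Wilcoxon rank-sum comparisons with
    Benjamini-Hochberg correction, one-vs-rest marker detection, and a
    negative-binomial UMI simulator with planted co-regulated modules for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
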