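Package: tgamir
Title: Integrative Blood miRNA-mRNA Analysis for Transposition of the
    Great Arteries Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a blood transcriptomics workflow
    for cohorts of patients with transposition of the great arteries (TGA)
    and matched controls: detection-rate filtering, quantile normalization,
    log2 transformation, unpaired t-test differential expression with
    Benjamini-Hochberg false discovery rate control and a dual fold-change
    threshold, delta-Ct qPCR relative quantification with a Ct gate and
    RNU6B reference normalization, inverse Spearman-correlation miRNA-mRNA
    network construction gated on 3'UTR binding sites, and ROC/AUC panels
    combining heart-failure markers with single miRNAs. Includes a synthetic
    cohort generator with planted ground truth for end-to-end validation,
    and packaged fixtures of the study's printed differential-expression
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
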