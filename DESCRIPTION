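Package: immunoclass
Title: Integrative Immune Transcriptomic Classification of Gastro-Oesophageal Adenocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies tumours of gastro-oesophageal adenocarcinoma cohorts
    into four immune microenvironment profiles (IIL-FL, IIL-FH, IIH-FL,
    IIH-FH) from bulk expression data: housekeeping-gene normalisation,
    marker-mean immune cell-type scores, an ssGSEA-style immune score,
    two-level unsupervised hierarchical classification (immune infiltrate
    and immune function), cross-class statistics (Kruskal-Wallis with FDR,
    rank-based differential expression, hypergeometric over-representation,
    preranked GSEA on hallmark sets), progression-free survival screening
    (L1-penalised Cox with cross-validation, maximally selected rank
    statistics, Kaplan-Meier/log-rank), and the test of whether the
    classification adds checkpoint-inhibitor response prediction beyond the
    PD-L1 combined positive score.  Includes a synthetic-cohort generator
    with planted ground truth so every stage can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
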