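Package: miRcohort
Title: Circulating miRNA qPCR Analysis for Case-Control and Case-Cohort
    Cardiovascular Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of circulating microRNA qPCR panels in
    epidemiological studies of coronary artery disease. Processes raw Ct
    tables with amplification-validity filtering, missingness filters,
    empirical-Bayes plate-effect correction and global mean normalization;
    performs case-control differential expression treating non-detects as
    right-censored observations (Kaplan-Meier restricted means, log-rank
    tests, fold changes, Benjamini-Hochberg correction); fits weighted Cox
    proportional-hazards models for case-cohort designs with Barlow or
    Prentice weighting; quantifies incremental predictive value over a
    baseline risk function via continuous and categorical net
    reclassification improvement, integrated discrimination improvement and
    weighted concordance with bootstrap confidence intervals; screens
    in-vitro expression matrices with empirical-Bayes moderated t and
    orthogonal polynomial trend tests; and interprets hits through
    score-filtered target sets, hypergeometric pathway enrichment and
    expressed-target overlap counts. Ships a synthetic-data generator that
    emulates the full study design so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml,
    fgsea,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
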