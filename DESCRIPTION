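Package: adrpanel
Title: Pharmacogenetic SNP-Panel Clustering and Adverse Drug Reaction Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for germline pharmacogenetic SNP panels in
    oncology cohorts. Loads and filters a curated variant-panel manifest,
    ingests per-patient VCFs into a binary carrier matrix, builds a
    patient-similarity network (Jaccard on carrier profiles) and partitions
    patients into clusters by deterministic greedy modularity optimisation,
    annotates clusters with variant, gene and drug sets (exclusivity counts
    and drug-proportion profiles), performs hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction, and estimates
    cluster-by-treatment odds ratios for adverse drug reactions with Woolf
    confidence intervals and the Haldane-Anscombe correction, including an
    exhaustive integer-table recovery oracle for published OR/CI pairs. A
    seeded synthetic-cohort generator emulates the study conditions so the
    whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    vcfR,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    withr
Config/testthat/edition: 3
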