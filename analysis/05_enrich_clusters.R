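#!/usr/bin/env Rscript
# Hypergeometric over-representation of the term map's gene sets within
# each cluster's gene set, BH-adjusted within cluster.

suppressMessages(library(adrpanel))
dir.create("results", showWarnings = FALSE)

panel <- filter_panel(load_panel("scratch/cohort_bundle/panel.tsv"))$manifest
gm <- read_genotype_matrix("scratch/genotype_matrix.tsv")
cl <- read_clustering("results/partition.tsv")
map <- read_gmt("scratch/cohort_bundle/terms.gmt")

ann <- annotate_clusters(cl, gm, panel)
gene_sets <- lapply(ann$clusters, `[[`, "genes")
enr <- enrich_clusters(gene_sets, map, alpha = 0.05)
readr::write_tsv(enr, "results/enrichment.tsv")

cat(sprintf("Tested %d (cluster, term) pairs over a %d-gene universe\n",
            nrow(enr), if (nrow(enr)) enr$N[1] else 0L))
cat("Significant at FDR 0.05:", sum(enr$significant), "\n")
top <- enr[!duplicated(enr$cluster), c("cluster", "term", "k", "K", "p", "q")]
cat("Top term per cluster:\n")
print(as.data.frame(top), row.names = FALSE)
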