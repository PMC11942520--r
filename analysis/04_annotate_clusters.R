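#!/usr/bin/env Rscript
# Map clusters to variant, gene and drug sets; compute the gene and drug
# exclusivity (Venn) counts and the per-drug cluster-proportion matrix.

suppressMessages(library(adrpanel))
dir.create("results", showWarnings = FALSE)

panel <- filter_panel(load_panel("scratch/cohort_bundle/panel.tsv"))$manifest
gm <- read_genotype_matrix("scratch/genotype_matrix.tsv")
cl <- read_clustering("results/partition.tsv")

ann <- annotate_clusters(cl, gm, panel, mode = "private")
print(ann)

gx <- gene_exclusivity(ann)
cat(sprintf("Exclusive genes per cluster: %s (total %d); shared histogram: %s; common to all: %d\n",
            paste(gx$exclusive, collapse = "/"), gx$n_exclusive,
            paste(gx$shared_histogram, collapse = "/"), gx$n_common_all))

prop <- drug_cluster_proportions(ann)
readr::write_tsv(tibble::as_tibble(prop, rownames = "drug"),
                 "results/drug_proportions.tsv")
dx <- drug_exclusivity(prop)
cat(sprintf("Exclusive drugs per cluster: %s; shared: %d; in all clusters: %d\n",
            paste(dx$exclusive, collapse = "/"), dx$n_shared, dx$n_common_all))
jsonlite::write_json(list(gene_exclusivity = gx, drug_exclusivity = dx),
                     "results/venn_summary.json", auto_unbox = TRUE, digits = NA)
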