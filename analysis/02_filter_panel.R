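#!/usr/bin/env Rscript
# Validate and filter the panel manifest: drop the design-excluded and
# duplicate entries, report the retained fraction and the gene-category
# composition of the analyzable set.

suppressMessages(library(adrpanel))
dir.create("results", showWarnings = FALSE)

panel <- load_panel("scratch/cohort_bundle/panel.tsv")
res <- filter_panel(panel)
write_panel(res$manifest, "scratch/panel_filtered.tsv")
jsonlite::write_json(res$report, "results/panel_filter_report.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("Panel: %d entries; %d design-excluded, %d duplicates -> %d retained (%.1f%%)\n",
            res$report$n_input, res$report$n_design_excluded,
            res$report$n_duplicates, res$report$n_retained,
            res$report$retained_fraction))
cats <- gene_category_summary(res$manifest)
cat(sprintf("Genes: %d across categories (transporter %d, phase I %d, phase II %d, DNA repair %d, other %d); %d intergenic variants\n",
            cats$n_genes, cats$transporter, cats$phase_I_metabolism,
            cats$phase_II_metabolism, cats$dna_repair,
            cats$other_target_signaling, cats$intergenic_variants))
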