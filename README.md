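# adrpanel

Pharmacogenetic SNP-panel clustering and adverse drug reaction (ADR)
association for oncology cohorts.

Chemotherapy regimens are usually dosed without regard to the patient's
germline pharmacogenetic background, although polymorphisms in drug
transporters, phase I/II metabolism enzymes and DNA-repair genes are
strongly associated with treatment toxicity. `adrpanel` implements, as a
tested and reusable R workflow, an analysis that stratifies patients by
their germline variant profile on a curated SNP panel and asks whether
the resulting patient clusters predict ADRs under specific treatments
(cisplatin, carboplatin, pemetrexed, radiotherapy and their
combinations). It is aimed at bioinformaticians and biostatisticians
reproducing or extending panel-based ADR-prediction analyses.

## What it computes

* **Panel filtering** — a TSV manifest of panel variants (rsID, hg19
  coordinates, gene, category, `drug|phenotype` annotations,
  design-exclusion and duplicate flags) is reduced to the analyzable
  set, with exact count conservation and truncated-percentage reporting
  (309/326 → 94.7%).
* **Cohort ingestion** — per-patient VCFs are matched to the panel by
  rsID or (chrom, pos, ref, alt) and collapsed to a binary carrier
  matrix *C* (patients × variants, 1 = at least one alternate allele),
  with a missing-call mask and QC counts (SNV/INDEL, per-chromosome).
* **Patient clustering** — a weighted network with Jaccard edge weights
  `s_ij = |C_i ∩ C_j| / |C_i ∪ C_j|`, thresholded (default 0.2),
  partitioned by a deterministic Louvain-style optimiser of the
  weighted Newman–Girvan modularity `Q = Σ_c (e_cc − a_c²)`.
* **Cluster annotation** — per-cluster variant/gene/drug sets,
  exclusivity (Venn) counts, and the drug-proportion matrix
  `p_dc = occurrences of drug d in cluster c / total occurrences of d`.
* **Enrichment** — hypergeometric upper tail `P(X ≥ k)` for term
  overlaps against a GMT term map, BH-adjusted within cluster.
* **Association** — cluster × treatment 2×2 tables against ADR status:
  `OR = ad/bc`, Woolf 95% CI
  `exp(ln OR ± 1.96 · sqrt(1/a + 1/b + 1/c + 1/d))`, Haldane–Anscombe
  +0.5 on all cells when a zero cell occurs, Pearson chi-square on the
  raw cells; plus `recover_table()`, an exhaustive enumerator that finds
  every integer table consistent with a printed OR/CI pair.
* **Synthetic cohorts** — `simulate_cohort()` generates seeded,
  byte-reproducible study inputs (panel TSV, one VCF per patient,
  clinical CSV, GMT, truth labels) with planted cluster structure and a
  logistic ADR model, so the full pipeline runs offline.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
default synthetic cohort (intermediate bulk goes to `scratch/`, summary
tables to `results/`). Running them in order prints, among other
things:

```
$ Rscript analysis/01_simulate_cohort.R
Patients: 70; ADR prevalence: 50.0%
Panel: 326 entries, 309 analyzable (94.7%)
Planted cluster sizes: 21/16/27/5/1

$ Rscript analysis/03_cluster_patients.R
Carrier matrix: 70 patients x 309 variants (308 SNVs, 1 INDEL, 1 on X)
Communities: 5 clusters (sizes 27/21/16/5/1), Q = 0.607
Stable across 10 repeated runs: TRUE
Adjusted Rand index vs planted clusters: 1.000

$ Rscript analysis/07_recover_published_tables.R
cisplatin/cluster0: 2 matching table(s), OR 5.25 (printed 5.25)
carboplatin/cluster1: 4 matching table(s), OR 4.58 (printed 4.58)
pemetrexed/cluster1: 2 matching table(s), OR 8.33 (printed 8.33)
```

The clustering recovers the five planted patient groups exactly
(ARI = 1.0; cluster indices are canonical, ordered by size). The last
script shows the association arithmetic at published scale: for
example, among 14 cisplatin-treated patients the table (7, 2, 2, 3) —
7 in-cluster patients with ADR, 2 without, versus 2 and 3 outside — is
the integer table whose Woolf interval rounds to (0.49, 56.80), and its
odds ratio is 5.25: in-cluster patients had 5.25 times the odds of an
ADR under cisplatin.

A minimal in-session example:

```r
library(adrpanel)
sim <- simulate_cohort(simulation_config(seed = 17))
g   <- build_patient_graph(sim$genotypes)           # Jaccard, threshold 0.2
cl  <- detect_communities(g, seed = 17)             # 5 clusters, Q ≈ 0.61
rows <- associate_all(sim$clinical, cl)             # OR per (treatment, cluster)
odds_ratio(contingency_table(7, 2, 2, 3))           # OR 5.25 (0.49-56.80)
```

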