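# Fixtures built in code: small panels, carrier matrices and graphs used
# across the test files.

# a hand-written panel manifest; drug annotations exercise combinations
# and phenotype categories
toy_panel <- function() {
  adrpanel:::new_panel_manifest(tibble::tibble(
    rsid = paste0("rs", 1:6),
    chrom = c("1", "1", "2", "7", "X", "3"),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    ref = c("A", "C", "G", "T", "A", "C"),
    alt = c("G", "T", "A", "C", "T", "CA"),
    gene = c("ABCB1", "ABCB1", "ERCC1", "GSTP1", "CYP2C19", ""),
    category = c("transporter", "transporter", "dna_repair",
                 "phase_II_metabolism", "phase_I_metabolism",
                 "other_target_signaling"),
    drug_annotations = c("Cisplatin|Toxicity",
                         "carboplatin/pemetrexed|Toxicity",
                         "cisplatin|Toxicity;cisplatin|Efficacy",
                         "radiotherapy|Toxicity",
                         "carboplatin|Toxicity",
                         ""),
    radiotoxicity = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    design_excluded = FALSE,
    duplicate_of = NA_character_
  ), provenance = "toy")
}

write_toy_panel_tsv <- function(panel = toy_panel(), path = tempfile(fileext = ".tsv")) {
  write_panel(panel, path)
  path
}

# carrier matrix from a named list patient -> rsid character vector
carrier_from_sets <- function(sets, variant_ids) {
  m <- t(vapply(sets, function(s) as.integer(variant_ids %in% s),
                integer(length(variant_ids))))
  colnames(m) <- variant_ids
  genotype_matrix(m)
}

# two disconnected triangles (unweighted cliques): nodes a-c and d-f
two_clique_graph <- function() {
  nodes <- letters[1:6]
  edges <- tibble::tibble(
    from = c("a", "a", "b", "d", "d", "e"),
    to = c("b", "c", "c", "e", "f", "f"),
    weight = 1)
  structure(list(nodes = nodes, edges = edges,
                 similarity_metric = "jaccard", edge_threshold = 0),
            class = "patient_graph")
}

complete_uniform_graph <- function(n = 6) {
  nodes <- sprintf("n%02d", seq_len(n))
  idx <- utils::combn(n, 2)
  structure(list(nodes = nodes,
                 edges = tibble::tibble(from = nodes[idx[1, ]],
                                        to = nodes[idx[2, ]], weight = 1),
                 similarity_metric = "jaccard", edge_threshold = 0),
            class = "patient_graph")
}

# small simulated cohort used where the full 70-patient default is overkill
small_sim_config <- function(seed = 11) {
  simulation_config(
    n_patients = 12, panel_size = 40, n_design_excluded = 3, n_duplicates = 1,
    cluster_sizes = c(5, 4, 3), block_sizes = c(14, 12, 10),
    treatment_counts = c(cisplatin = 4, carboplatin = 5, pemetrexed = 3,
                         radiotherapy = 4),
    seed = seed)
}

# clinical table with planted marginal counts (no cluster structure)
planted_clinical <- function(n = 70, n_adr = 37, n_stage_iv = min(20, n)) {
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = 65, sex = "male",
    stage = rep(c("IV", "IIIA"), c(n_stage_iv, n - n_stage_iv)),
    treatments = "other",
    adr_any = seq_len(n) <= n_adr,
    adr_categories = ifelse(seq_len(n) <= n_adr, "hematologic", ""))
}

truth_clustering <- function(config) {
  labels <- rep(seq_along(config$cluster_sizes) - 1L, config$cluster_sizes)
  names(labels) <- sprintf("P%03d", seq_len(config$n_patients))
  clustering_from_labels(labels)
}
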