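# build a cluster_annotation directly from gene/variant sets, bypassing
# the genotype layer, for exclusivity arithmetic tests
annotation_from_sets <- function(gene_sets, variant_sets = NULL, ann = NULL) {
  `%||%` <- function(a, b) if (is.null(a)) b else a
  clusters <- lapply(seq_along(gene_sets), function(i) {
    list(cluster = i - 1L,
         variants = variant_sets[[i]] %||% character(0),
         genes = gene_sets[[i]], drugs = character(0),
         n_patients = 1L, n_variants = length(variant_sets[[i]] %||% character(0)),
         n_genes = length(gene_sets[[i]]))
  })
  structure(list(clusters = stats::setNames(clusters,
                                            as.character(seq_along(gene_sets) - 1)),
                 mode = "private",
                 annotations = ann %||% tibble::tibble(rsid = character(0),
                                                       gene = character(0),
                                                       drug = character(0),
                                                       phenotype_category = character(0))),
            class = "cluster_annotation")
}

test_that("variant assignment distinguishes private from union mode", {
  ids <- paste0("v", 1:4)
  gm <- carrier_from_sets(list(P1 = "v1", P2 = "v2", P3 = "v3",
                               P4 = c("v3", "v4")), ids)
  lab <- stats::setNames(c(0L, 0L, 1L, 1L), paste0("P", 1:4))
  cl <- clustering_from_labels(lab)

  priv <- assign_cluster_variants(cl, gm, mode = "private")
  expect_setequal(priv[["0"]], c("v1", "v2"))
  expect_setequal(priv[["1"]], c("v3", "v4"))

  # a variant carried in two clusters is private to neither, union to both
  gm2 <- carrier_from_sets(list(P1 = c("v1", "v3"), P2 = "v2", P3 = "v3",
                                P4 = "v4"), ids)
  priv2 <- assign_cluster_variants(cl, gm2, mode = "private")
  expect_false("v3" %in% unlist(priv2))
  uni2 <- assign_cluster_variants(cl, gm2, mode = "union")
  expect_true("v3" %in% uni2[["0"]] && "v3" %in% uni2[["1"]])

  # private sets are pairwise disjoint by construction
  sim <- simulate_cohort(small_sim_config())
  clt <- truth_clustering(sim$config)
  sets <- assign_cluster_variants(clt, sim$genotypes, mode = "private")
  expect_equal(anyDuplicated(unlist(sets)), 0)
})

test_that("empty clusters yield empty variant sets", {
  gm <- carrier_from_sets(list(P1 = "v1", P2 = "v2"), c("v1", "v2"))
  lab <- stats::setNames(c(0L, 0L), c("P1", "P2"))
  cl <- clustering_from_labels(lab)
  sets <- assign_cluster_variants(cl, gm)
  expect_equal(length(sets), 1)
})

test_that("gene exclusivity reproduces engineered Venn counts", {
  # five clusters with exclusive gene counts 47/37/45/12/5 (total 146)
  # plus 30 genes shared by two or three clusters and none common to all
  excl_counts <- c(47, 37, 45, 12, 5)
  gene_sets <- lapply(seq_along(excl_counts), function(i) {
    sprintf("EX%d_%03d", i, seq_len(excl_counts[i]))
  })
  shared2 <- sprintf("SH2_%03d", 1:18)   # in clusters 1 and 2
  shared3 <- sprintf("SH3_%03d", 1:12)   # in clusters 1, 2, 3
  gene_sets[[1]] <- c(gene_sets[[1]], shared2, shared3)
  gene_sets[[2]] <- c(gene_sets[[2]], shared2, shared3)
  gene_sets[[3]] <- c(gene_sets[[3]], shared3)
  ann <- annotation_from_sets(gene_sets)
  gx <- gene_exclusivity(ann)
  expect_equal(unname(gx$exclusive), excl_counts)
  expect_equal(gx$n_exclusive, 146)
  expect_equal(sum(gx$exclusive), gx$n_exclusive)
  # 30 genes shared by no more than three clusters
  expect_equal(gx$shared_histogram[["2"]] + gx$shared_histogram[["3"]], 30)
  expect_equal(gx$n_common_all, 0)
})

test_that("gene exclusivity handles the degenerate cluster layouts", {
  ann1 <- annotation_from_sets(list(c("g1", "g2", "g3")))
  gx1 <- gene_exclusivity(ann1)
  expect_equal(unname(gx1$exclusive), 3)  # one cluster: everything exclusive

  ann2 <- annotation_from_sets(list(c("g1", "g2"), c("g1", "g3"), c("g1")))
  gx2 <- gene_exclusivity(ann2)
  expect_equal(gx2$n_common_all, 1)       # g1 everywhere
  expect_equal(gx2$shared_histogram[["3"]], 1)
  expect_equal(gx2$n_exclusive, 2)
})

test_that("drug proportions are occurrence ratios normalized per drug", {
  ann_tbl <- tibble::tibble(
    rsid = c("v1", "v2", "v3", "v4"),
    gene = "G",
    drug = c("drugd", "drugd", "drugd", "solo"),
    phenotype_category = "Toxicity")
  ann <- annotation_from_sets(
    gene_sets = list("G", "G"),
    variant_sets = list(c("v1", "v2", "v4"), "v3"),
    ann = ann_tbl)
  prop <- drug_cluster_proportions(ann)
  expect_equal(unname(prop["drugd", ]), c(2 / 3, 1 / 3))
  expect_equal(unname(prop["solo", ]), c(1, 0))
  expect_equal(unname(rowSums(prop)), rep(1, nrow(prop)))
})

test_that("a 9-of-12 radiotherapy placement gives proportion 0.75", {
  ann_tbl <- tibble::tibble(
    rsid = sprintf("v%02d", 1:12), gene = "G",
    drug = "radiotherapy", phenotype_category = "Toxicity")
  ann <- annotation_from_sets(
    gene_sets = list("G", "G"),
    variant_sets = list(sprintf("v%02d", 1:9), sprintf("v%02d", 10:12)),
    ann = ann_tbl)
  prop <- drug_cluster_proportions(ann)
  expect_equal(unname(prop["radiotherapy", "0"]), 0.75)
})

test_that("proportion rows sum to one on simulated cohorts", {
  for (seed in c(11, 12)) {
    sim <- simulate_cohort(small_sim_config(seed))
    ann <- annotate_clusters(truth_clustering(sim$config), sim$genotypes,
                             sim$panel_filtered)
    prop <- drug_cluster_proportions(ann)
    expect_true(all(abs(rowSums(prop) - 1) < 1e-12))
    expect_true(all(prop >= 0 & prop <= 1))
  }
})

test_that("drug exclusivity reproduces engineered counts", {
  # 5 clusters; exclusives 3/14/7/2/0; 41 shared, 12 of them in all five
  excl <- c(3, 14, 7, 2, 0)
  rows <- list()
  for (i in seq_along(excl)) {
    if (excl[i] > 0) {
      m <- matrix(0, excl[i], 5)
      m[, i] <- 1
      rows[[length(rows) + 1]] <- m
    }
  }
  m_all <- matrix(1, 12, 5)                      # common to all clusters
  m_two <- matrix(0, 29, 5); m_two[, 1:2] <- 1   # the other shared drugs
  rows <- c(rows, list(m_all, m_two))
  prop <- do.call(rbind, rows)
  prop <- sweep(prop, 1, rowSums(prop), "/")
  rownames(prop) <- sprintf("drug%02d", seq_len(nrow(prop)))
  colnames(prop) <- as.character(0:4)
  dx <- drug_exclusivity(prop)
  expect_equal(unname(dx$exclusive), excl)
  expect_equal(dx$n_shared, 41)
  expect_equal(dx$n_common_all, 12)
})

test_that("drug exclusivity classifies single rows correctly", {
  prop <- matrix(c(0, 1, 0, 0.5, 0.3, 0.2), 2, 3, byrow = TRUE,
                 dimnames = list(c("only1", "everywhere"), 0:2))
  dx <- drug_exclusivity(prop)
  expect_equal(unname(dx$exclusive), c(0L, 1L, 0L))
  expect_equal(dx$n_shared, 1)
  expect_equal(dx$n_common_all, 1)
  expect_error(drug_exclusivity(prop[0, , drop = FALSE]), "empty")
})
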