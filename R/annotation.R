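# Cluster -> variant / gene / drug annotation: exclusivity (Venn) counts
# and the per-drug cluster-proportion statistic.

#' Assign panel variants to clusters
#'
#' `mode = "private"` (default): a variant belongs to a cluster only if
#' every patient carrying it is a member of that cluster, so cluster
#' variant sets are pairwise disjoint and a variant carried in two
#' clusters belongs to neither. `mode = "union"`: a variant belongs to
#' every cluster with at least one carrier.
#'
#' @param clustering A `clustering` whose labels cover the matrix patients.
#' @param gm A `genotype_matrix`.
#' @param mode "private" or "union".
#' @return Named list (cluster index as character) of rsid character
#'   vectors; empty clusters yield empty sets.
#' @export
assign_cluster_variants <- function(clustering, gm, mode = c("private", "union")) {
  mode <- match.arg(mode)
  if (!all(gm$patient_ids %in% names(clustering$labels))) {
    stop("clustering labels must cover all matrix patients")
  }
  lab <- clustering$labels[gm$patient_ids]
  clusters <- sort(unique(unname(clustering$labels)))
  carrier <- gm$carrier > 0
  sets <- lapply(clusters, function(cl) {
    members <- lab == cl
    carried_in <- colSums(carrier[members, , drop = FALSE]) > 0
    if (mode == "union") {
      gm$variant_ids[carried_in]
    } else {
      carried_out <- colSums(carrier[!members, , drop = FALSE]) > 0
      gm$variant_ids[carried_in & !carried_out]
    }
  })
  stats::setNames(sets, as.character(clusters))
}

#' Annotate clusters with variant, gene and drug sets
#'
#' @param clustering A `clustering`.
#' @param gm A `genotype_matrix`.
#' @param panel The filtered `panel_manifest`.
#' @param mode Variant assignment mode, see [assign_cluster_variants()].
#' @param phenotype_filter Passed to [panel_drug_annotations()].
#' @return A `cluster_annotation`: per cluster the variant set, gene set
#'   (genes of the cluster's variants), drug set (drugs annotated to any
#'   of the cluster's variants) and patient/gene/variant counts.
#' @export
annotate_clusters <- function(clustering, gm, panel, mode = "private",
                              phenotype_filter = "Toxicity") {
  variant_sets <- assign_cluster_variants(clustering, gm, mode)
  ann <- panel_drug_annotations(panel, phenotype_filter)
  per_cluster <- lapply(names(variant_sets), function(cl) {
    vs <- variant_sets[[cl]]
    genes <- unique(panel$gene[panel$rsid %in% vs & nzchar(panel$gene)])
    drugs <- unique(ann$drug[ann$rsid %in% vs])
    list(cluster = as.integer(cl),
         variants = vs, genes = genes, drugs = drugs,
         n_patients = sum(clustering$labels == as.integer(cl)),
         n_variants = length(vs), n_genes = length(genes))
  })
  structure(list(clusters = stats::setNames(per_cluster, names(variant_sets)),
                 mode = mode, annotations = ann),
            class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat("<cluster_annotation> (", x$mode, " assignment)\n", sep = "")
  for (cl in x$clusters) {
    cat(sprintf("  cluster %d: %d patients, %d variants, %d genes, %d drugs\n",
                cl$cluster, cl$n_patients, cl$n_variants, cl$n_genes,
                length(cl$drugs)))
  }
  invisible(x)
}

#' Gene exclusivity (Venn) counts across clusters
#'
#' @param annotation A `cluster_annotation`.
#' @return List with `exclusive` (named per-cluster counts of genes found
#'   in exactly one cluster's gene set), `n_exclusive` (their total),
#'   `shared_histogram` (named counts: number of genes present in exactly
#'   k clusters, k >= 1) and `n_common_all` (genes in every cluster).
#' @export
gene_exclusivity <- function(annotation) {
  gene_sets <- lapply(annotation$clusters, `[[`, "genes")
  if (length(gene_sets) < 1) stop("need at least one cluster")
  all_genes <- unique(unlist(gene_sets))
  in_k <- vapply(all_genes, function(g) {
    sum(vapply(gene_sets, function(s) g %in% s, logical(1)))
  }, integer(1))
  exclusive <- vapply(gene_sets, function(s) {
    sum(all_genes[in_k == 1] %in% s)
  }, integer(1))
  hist <- table(factor(in_k, levels = seq_len(length(gene_sets))))
  list(exclusive = exclusive,
       n_exclusive = sum(in_k == 1),
       shared_histogram = stats::setNames(as.integer(hist), names(hist)),
       n_common_all = sum(in_k == length(gene_sets)))
}

#' Drug-proportion matrix across clusters
#'
#' One "occurrence" is a distinct (variant, drug) annotation pair, counted
#' in the cluster holding the variant. Each drug's row is normalized by
#' its total occurrences, so rows sum to 1 over the clusters where the
#' drug occurs; drugs with zero occurrences in every cluster are omitted.
#'
#' @param annotation A `cluster_annotation`.
#' @return Numeric matrix, drugs x clusters, rows summing to 1.
#' @export
drug_cluster_proportions <- function(annotation) {
  clusters <- names(annotation$clusters)
  ann <- annotation$annotations
  counts <- vapply(clusters, function(cl) {
    vs <- annotation$clusters[[cl]]$variants
    hits <- ann[ann$rsid %in% vs, , drop = FALSE]
    tab <- table(factor(hits$drug, levels = sort(unique(ann$drug))))
    as.integer(tab)
  }, integer(length(sort(unique(ann$drug)))))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  rownames(counts) <- sort(unique(ann$drug))
  colnames(counts) <- clusters
  totals <- rowSums(counts)
  counts <- counts[totals > 0, , drop = FALSE]
  sweep(counts, 1, rowSums(counts), "/")
}

#' Drug exclusivity counts from a proportion matrix
#'
#' @param prop Drug x cluster proportion (or count) matrix.
#' @return List with `exclusive` (per-cluster counts of drugs nonzero in
#'   exactly that one cluster), `n_shared` (drugs nonzero in >= 2
#'   clusters) and `n_common_all` (drugs nonzero in every cluster).
#' @export
drug_exclusivity <- function(prop) {
  if (length(prop) == 0 || nrow(prop) == 0) stop("proportion matrix is empty")
  nz <- prop > 0
  n_clusters_per_drug <- rowSums(nz)
  exclusive <- vapply(seq_len(ncol(nz)), function(j) {
    sum(nz[, j] & n_clusters_per_drug == 1)
  }, integer(1))
  names(exclusive) <- colnames(prop)
  list(exclusive = exclusive,
       n_shared = sum(n_clusters_per_drug >= 2),
       n_common_all = sum(n_clusters_per_drug == ncol(nz)))
}
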