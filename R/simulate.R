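# Seeded synthetic-cohort generator: panel manifest, genotypes (and
# per-patient VCFs), clinical table, term map and truth labels with the
# statistical structure the downstream analysis assumes.

SIM_DRUGS <- c("cisplatin", "carboplatin", "pemetrexed", "docetaxel",
               "gemcitabine", "vinorelbine", "paclitaxel", "etoposide",
               "fluorouracil", "irinotecan", "methotrexate", "erlotinib")

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 70 patients, a 326-entry panel
#' of which 15 are design-excluded and 2 duplicates (309 analyzable), five
#' planted clusters of sizes 21/16/27/5/1, carrier probability 0.8 inside
#' a cluster's own variant block and 0.05 elsewhere, ADR base rate 0.528,
#' and the treatment mix cisplatin 14 / carboplatin 30 (14 of whom also
#' receive pemetrexed) / radiotherapy 17.
#'
#' @param n_patients Cohort size.
#' @param panel_size Panel entries before filtering.
#' @param n_design_excluded,n_duplicates Flagged panel rows.
#' @param cluster_sizes Planted cluster sizes (must sum to `n_patients`).
#' @param within_cluster_carrier_prob,between_cluster_carrier_prob Carrier
#'   probabilities for a cluster's own block vs other blocks.
#' @param adr_base_rate Baseline ADR probability (logistic intercept scale).
#' @param treatment_counts Named counts; pemetrexed patients are drawn
#'   from the carboplatin-treated.
#' @param effect_log_odds Optional data frame (`cluster`, `treatment`,
#'   `log_odds`): additive log-odds shifts applied to patients of that
#'   cluster receiving that treatment. NULL = no effects.
#' @param block_sizes Per-cluster variant-block sizes; the default splits
#'   the analyzable variants proportionally to the study's per-cluster
#'   exclusive-gene counts (47/37/45/12/5).
#' @param seed Integer master seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 70,
                              panel_size = 326,
                              n_design_excluded = 15,
                              n_duplicates = 2,
                              cluster_sizes = c(21, 16, 27, 5, 1),
                              within_cluster_carrier_prob = 0.8,
                              between_cluster_carrier_prob = 0.05,
                              adr_base_rate = 0.528,
                              treatment_counts = c(cisplatin = 14, carboplatin = 30,
                                                   pemetrexed = 14, radiotherapy = 17),
                              effect_log_odds = NULL,
                              block_sizes = NULL,
                              seed = 17L) {
  cfg <- list(n_patients = n_patients, panel_size = panel_size,
              n_design_excluded = n_design_excluded, n_duplicates = n_duplicates,
              cluster_sizes = cluster_sizes,
              within_cluster_carrier_prob = within_cluster_carrier_prob,
              between_cluster_carrier_prob = between_cluster_carrier_prob,
              adr_base_rate = adr_base_rate,
              treatment_counts = treatment_counts,
              effect_log_odds = effect_log_odds,
              block_sizes = block_sizes,
              seed = as.integer(seed))
  if (sum(cluster_sizes) != n_patients) {
    stop("cluster sizes (", sum(cluster_sizes), ") must sum to n_patients (",
         n_patients, ")")
  }
  probs <- c(within_cluster_carrier_prob, between_cluster_carrier_prob, adr_base_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(treatment_counts > n_patients)) stop("treatment counts exceed n_patients")
  if (n_design_excluded + n_duplicates >= panel_size) stop("nothing left after flags")
  n_analyzable <- panel_size - n_design_excluded - n_duplicates
  if (is.null(cfg$block_sizes)) {
    w <- c(47, 37, 45, 12, 5)[seq_along(cluster_sizes)]
    if (length(w) < length(cluster_sizes)) w <- rep(1, length(cluster_sizes))
    raw <- n_analyzable * w / sum(w)
    bs <- floor(raw)
    rem <- n_analyzable - sum(bs)
    if (rem > 0) {
      top <- order(raw - bs, decreasing = TRUE)[seq_len(rem)]
      bs[top] <- bs[top] + 1
    }
    cfg$block_sizes <- bs
  }
  if (sum(cfg$block_sizes) != n_analyzable) {
    stop("block sizes must sum to the analyzable panel size (", n_analyzable, ")")
  }
  structure(cfg, class = "simulation_config")
}

# per-patient counter-based substream: patient i's draws never depend on
# how many patients follow them
patient_seed <- function(seed, i, salt = 0L) {
  (as.integer(seed) %% 100000L) * 20011L + 131L * as.integer(i) + as.integer(salt)
}

#' Simulate a complete synthetic cohort
#'
#' Generates, from one seed: a panel manifest with gene / category / drug
#' annotations and flagged rows; a carrier matrix in which each planted
#' cluster owns a disjoint block of variants (carried with the
#' within-cluster probability by members and the between-cluster
#' probability by everyone else); a clinical table whose ADR outcomes are
#' drawn from logit(P(ADR)) = logit(base rate) + sum of the configured
#' (cluster, treatment) log-odds effects; genotype strings for VCF
#' emission; a term map over the panel genes; and the truth labels.
#' Identical seeds give identical objects (and byte-identical files via
#' [write_cohort_bundle()]).
#'
#' @param config A `simulation_config`.
#' @return A `cohort_sim` list: `panel` (full manifest incl. flagged
#'   rows), `panel_filtered`, `genotypes` (a `genotype_matrix` over the
#'   analyzable variants), `gt_strings` (patient x variant genotype
#'   strings for VCF output), `clinical`, `term_map`, `truth` (cluster
#'   labels, block map, effects) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- simulate_panel(config)
  filt <- filter_panel(panel)
  truth_cluster <- rep(seq_along(config$cluster_sizes) - 1L, config$cluster_sizes)
  patient_ids <- sprintf("P%03d", seq_len(config$n_patients))
  names(truth_cluster) <- patient_ids
  block_of <- rep(seq_along(config$block_sizes) - 1L, config$block_sizes)

  # genotypes: per-patient substreams
  n_var <- nrow(filt$manifest)
  carrier <- matrix(0L, config$n_patients, n_var,
                    dimnames = list(patient_ids, filt$manifest$rsid))
  gt <- matrix("0/0", config$n_patients, n_var,
               dimnames = list(patient_ids, filt$manifest$rsid))
  for (i in seq_len(config$n_patients)) {
    set.seed(patient_seed(config$seed, i, salt = 1L))
    p <- ifelse(block_of == truth_cluster[i],
                config$within_cluster_carrier_prob,
                config$between_cluster_carrier_prob)
    x <- stats::rbinom(n_var, 1, p)
    carrier[i, ] <- x
    hom <- stats::rbinom(n_var, 1, 0.1)  # a minority of carriers homozygous
    gt[i, x == 1] <- ifelse(hom[x == 1] == 1, "1/1", "0/1")
  }
  gm <- genotype_matrix(carrier)

  clinical <- simulate_clinical(config, truth_cluster, patient_ids)
  term_map <- simulate_term_map(filt$manifest, config$seed)
  structure(list(panel = panel, panel_filtered = filt$manifest,
                 filter_report = filt$report,
                 genotypes = gm, gt_strings = gt, clinical = clinical,
                 term_map = term_map,
                 truth = list(cluster = truth_cluster, block_of_variant =
                                stats::setNames(block_of, filt$manifest$rsid),
                              effect_log_odds = config$effect_log_odds),
                 config = config),
            class = "cohort_sim")
}

simulate_panel <- function(config) {
  set.seed(patient_seed(config$seed, 0L, salt = 2L))
  n <- config$panel_size
  n_intergenic <- min(5L, max(0L, n - 10L))
  n_genes <- min(176L, n - n_intergenic)  # 176 genes at the full panel size
  gene_pool <- sprintf("GENE%03d", seq_len(n_genes))
  cat_of_gene <- sample(rep(PANEL_CATEGORIES,
                            length.out = n_genes))  # gene -> fixed category
  names(cat_of_gene) <- gene_pool
  # every gene used at least once; remaining variants reuse genes; five
  # variants are intergenic (non-coding regions)
  gene_of <- c(gene_pool, sample(gene_pool, n - n_genes - n_intergenic, replace = TRUE),
               rep("", n_intergenic))
  gene_of <- sample(gene_of)
  bases <- c("A", "C", "G", "T")
  chrom <- sample(as.character(1:22), n, replace = TRUE)
  x_idx <- sample(n, 1)
  chrom[x_idx] <- "X"  # a single panel variant on the X chromosome
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  indel_idx <- sample(setdiff(seq_len(n), x_idx), 1)  # a single INDEL
  alt[indel_idx] <- paste0(ref[indel_idx], "A")
  # drug annotations: 1-3 toxicity-annotated drugs per genic variant
  radio_idx <- sample(which(nzchar(gene_of)),
                      min(15L, sum(nzchar(gene_of))))  # radiotoxicity variants
  ann <- vapply(seq_len(n), function(i) {
    if (!nzchar(gene_of[i])) return("")
    k <- sample(1:3, 1)
    drugs <- sample(SIM_DRUGS, k, prob = c(8, 10, 6, rep(2, length(SIM_DRUGS) - 3)))
    pairs <- paste0(drugs, "|Toxicity")
    if (i %in% radio_idx) pairs <- c(pairs, "radiotherapy|Toxicity")
    join_semi(pairs)
  }, character(1))
  man <- tibble::tibble(
    rsid = sprintf("rs%07d", 1000000 + seq_len(n)),
    chrom = chrom,
    pos = sort(sample(1e4:1e8, n)),
    ref = ref, alt = alt,
    gene = gene_of,
    category = ifelse(nzchar(gene_of), cat_of_gene[gene_of],
                      "other_target_signaling"),
    drug_annotations = ann,
    radiotoxicity = seq_len(n) %in% radio_idx,
    design_excluded = FALSE,
    duplicate_of = NA_character_
  )
  flagged <- sample(n, config$n_design_excluded + config$n_duplicates)
  excl <- flagged[seq_len(config$n_design_excluded)]
  dup <- setdiff(flagged, excl)
  man$design_excluded[excl] <- TRUE
  keep_of <- setdiff(seq_len(n), flagged)
  resample <- function(x) x[sample.int(length(x), 1)]
  for (j in dup) {
    earlier <- keep_of[keep_of < j]
    man$duplicate_of[j] <- man$rsid[resample(if (length(earlier)) earlier else keep_of)]
  }
  new_panel_manifest(man, provenance = paste0("synthetic panel, seed ", config$seed))
}

#' Simulate the clinical table alone
#'
#' Draws treatments, demographics and ADR outcomes for given true cluster
#' labels without regenerating the panel or genotypes — useful for
#' replicate studies of the outcome model (the genotype layer is
#' unchanged across replicates by design).
#'
#' @param config A `simulation_config` (its `seed` drives all draws).
#' @param truth_cluster Named integer vector patient -> true cluster.
#' @param patient_ids Patient identifiers (defaults to the names of
#'   `truth_cluster`).
#' @return Clinical tibble as in [read_clinical()].
#' @export
simulate_clinical <- function(config, truth_cluster,
                              patient_ids = names(truth_cluster)) {
  n <- config$n_patients
  tc <- config$treatment_counts
  set.seed(patient_seed(config$seed, 0L, salt = 3L))  # cohort-level design stream
  cis <- sample(n, tc[["cisplatin"]])
  carb <- sample(setdiff(seq_len(n), cis), tc[["carboplatin"]])
  pem <- sample(carb, min(tc[["pemetrexed"]], length(carb)))
  radio <- sample(n, tc[["radiotherapy"]])
  other <- setdiff(seq_len(n), c(cis, carb))
  treatments <- vapply(seq_len(n), function(i) {
    t <- c(if (i %in% cis) "cisplatin", if (i %in% carb) "carboplatin",
           if (i %in% pem) "pemetrexed", if (i %in% radio) "radiotherapy",
           if (i %in% other) "other")
    join_semi(t)
  }, character(1))
  age <- pmin(pmax(round(stats::rnorm(n, 69.5, 7.8)), 40), 89)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.7, 0.3))
  stages <- c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IV")
  stage <- sample(stages, n, replace = TRUE,
                  prob = c(6, 7, 11, 7, 13, 6, 20) / 70)
  # ADR outcomes: per-patient substreams, logistic model on the true cluster
  eff <- config$effect_log_odds
  adr_any <- logical(n)
  adr_cat <- character(n)
  cat_prob <- c(14, 7, 13, 2, 8, 5)  # Table-1-like toxicity mix
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i, salt = 4L))
    lp <- stats::qlogis(config$adr_base_rate)
    if (!is.null(eff) && nrow(eff) > 0) {
      tx <- split_semi(treatments[i])
      hit <- eff$cluster == truth_cluster[i] & eff$treatment %in% tx
      lp <- lp + sum(eff$log_odds[hit])
    }
    adr_any[i] <- stats::runif(1) < stats::plogis(lp)
    if (adr_any[i]) {
      k <- sample(1:2, 1, prob = c(0.75, 0.25))
      adr_cat[i] <- join_semi(sample(ADR_CATEGORIES, k, prob = cat_prob))
    }
  }
  tibble::tibble(patient_id = patient_ids, age = age, sex = sex, stage = stage,
                 treatments = treatments, adr_any = adr_any,
                 adr_categories = adr_cat)
}

simulate_term_map <- function(panel, seed) {
  set.seed(patient_seed(seed, 0L, salt = 5L))
  genes <- unique(panel$gene[nzchar(panel$gene)])
  terms <- list()
  ns <- character(0)
  # category-driven terms (coherent biology) plus random BP/MF terms
  for (cat in PANEL_CATEGORIES) {
    g <- unique(panel$gene[panel$category == cat & nzchar(panel$gene)])
    if (length(g) >= 3) {
      id <- paste0("TERM_", toupper(cat))
      terms[[id]] <- sort(g)
      ns[id] <- "MF"
    }
  }
  for (k in seq_len(20)) {
    id <- sprintf("TERM_BP%03d", k)
    terms[[id]] <- sort(sample(genes, sample(5:30, 1)))
    ns[id] <- "BP"
  }
  term_gene_map(terms, universe = sort(genes),
                names = stats::setNames(gsub("_", " ", tolower(names(terms))),
                                        names(terms)),
                namespace = ns)
}

#' Build a cohort that yields a requested 2x2 table exactly
#'
#' Deterministic fixture builder: assigns treatment, cluster membership
#' and ADR flags so that [build_contingency()] under the requested
#' convention reproduces the planted table cell for cell.
#'
#' @param table A `contingency_table` (or list with a, b, c, d).
#' @param treatment Treatment label planted.
#' @param cluster Cluster index the (a, b) row refers to.
#' @param convention "A" (in/out of cluster among treated) or "B"
#'   (treated/untreated within the cluster).
#' @param n_patients Optional cohort size >= table total; padding patients
#'   are untreated, ADR-free and placed outside the cluster (convention A)
#'   or in another cluster (convention B).
#' @return List with `clinical` (tibble) and `clustering`.
#' @export
make_planted_table_cohort <- function(table, treatment, cluster = 0L,
                                      convention = c("A", "B"),
                                      n_patients = NULL) {
  convention <- match.arg(convention)
  if (!inherits(table, "contingency_table")) {
    table <- do.call(contingency_table, as.list(stats::setNames(
      as.numeric(unlist(table)[1:4]), c("a", "b", "c", "d"))))
  }
  total <- table$a + table$b + table$c + table$d
  if (total == 0) stop("empty table is infeasible")
  n_patients <- n_patients %||% total
  if (n_patients < total) stop("n_patients smaller than table total")
  ids <- sprintf("P%03d", seq_len(n_patients))
  other_cluster <- cluster + 1L
  treated <- adr <- logical(n_patients)
  clust <- rep(other_cluster, n_patients)
  idx <- 0
  place <- function(k, in_cluster, is_treated, has_adr) {
    if (k > 0) {
      sel <- idx + seq_len(k)
      clust[sel] <<- if (in_cluster) cluster else other_cluster
      treated[sel] <<- is_treated
      adr[sel] <<- has_adr
      idx <<- idx + k
    }
  }
  if (convention == "A") {
    place(table$a, TRUE, TRUE, TRUE)
    place(table$b, TRUE, TRUE, FALSE)
    place(table$c, FALSE, TRUE, TRUE)
    place(table$d, FALSE, TRUE, FALSE)
  } else {
    place(table$a, TRUE, TRUE, TRUE)
    place(table$b, TRUE, TRUE, FALSE)
    place(table$c, TRUE, FALSE, TRUE)
    place(table$d, TRUE, FALSE, FALSE)
  }
  clinical <- tibble::tibble(
    patient_id = ids, age = 65, sex = "male", stage = "IV",
    treatments = ifelse(treated, treatment, "other"),
    adr_any = adr,
    adr_categories = ifelse(adr, "hematologic", ""))
  labels <- stats::setNames(as.integer(clust), ids)
  clustering <- structure(list(labels = labels, Q = NA_real_,
                               n_clusters = length(unique(labels)),
                               seed = NA_integer_, resolution = 1),
                          class = "clustering")
  list(clinical = clinical, clustering = clustering)
}

#' Write a simulated cohort to a file bundle
#'
#' Emits `panel.tsv`, `clinical.csv`, `terms.gmt`, `truth.json` and one
#' standard-conformant single-sample VCF per patient under `cohort/`.
#' Deterministic: the same `cohort_sim` always produces byte-identical
#' files.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_cohort_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(file.path(dir, "cohort"), recursive = TRUE, showWarnings = FALSE)
  write_panel(sim$panel, file.path(dir, "panel.tsv"))
  write_clinical(sim$clinical, file.path(dir, "clinical.csv"))
  write_gmt(sim$term_map, file.path(dir, "terms.gmt"))
  jsonlite::write_json(
    list(cluster = as.list(sim$truth$cluster),
         block_of_variant = as.list(sim$truth$block_of_variant),
         effect_log_odds = sim$truth$effect_log_odds,
         seed = sim$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  panel <- sim$panel_filtered
  for (pid in sim$genotypes$patient_ids) {
    write_patient_vcf(pid, panel, sim$gt_strings[pid, ],
                      file.path(dir, "cohort", paste0(pid, ".vcf")))
  }
  invisible(dir)
}

write_patient_vcf <- function(patient_id, panel, gt_row, path) {
  ord <- order(chrom_rank(panel$chrom), panel$pos)
  contigs <- unique(panel$chrom[ord])
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=hg19",
    paste0("##contig=<ID=", contigs, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", patient_id, sep = "\t"))
  body <- paste(panel$chrom[ord], panel$pos[ord], panel$rsid[ord],
                panel$ref[ord], panel$alt[ord], "50", "PASS", ".",
                "GT", gt_row[ord], sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.integer(chrom))
  r[chrom == "X"] <- 23L
  r[chrom == "Y"] <- 24L
  r
}
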