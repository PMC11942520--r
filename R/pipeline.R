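# End-to-end orchestration over file inputs, plus the per-patient report.

REPORT_BANNER <- "Research use only - not a clinical device."

#' Validate a pipeline run configuration
#'
#' @param config Named list (or YAML path) with `panel` (TSV), `vcf_dir`
#'   (directory of per-patient VCFs) or `vcfs` (explicit paths),
#'   `clinical` (CSV), `gmt` (term file), `out_dir`, and optional stage
#'   parameters `metric`, `edge_threshold`, `resolution`, `seed`,
#'   `convention`, `z`, `alpha`, `genotype_coding`.
#' @return The completed config list; errors on missing files or
#'   out-of-range parameters, before anything is executed.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  defaults <- list(metric = "jaccard", edge_threshold = 0.2, resolution = 1,
                   seed = 17L, convention = "A", z = 1.96, alpha = 0.05,
                   genotype_coding = "carrier")
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  for (nm in c("panel", "clinical", "gmt")) {
    if (is.null(config[[nm]])) stop("run config missing '", nm, "'")
    if (!file.exists(config[[nm]])) stop("run config: file not found: ", config[[nm]])
  }
  if (is.null(config$vcfs)) {
    if (is.null(config$vcf_dir) || !dir.exists(config$vcf_dir)) {
      stop("run config: vcf_dir missing or not a directory")
    }
    config$vcfs <- sort(list.files(config$vcf_dir, pattern = "\\.vcf(\\.gz)?$",
                                   full.names = TRUE))
  }
  if (length(config$vcfs) == 0) stop("run config: no VCF files found")
  if (is.null(config$out_dir)) stop("run config missing 'out_dir'")
  if (config$edge_threshold < 0 || config$edge_threshold > 1) {
    stop("edge_threshold outside [0, 1]")
  }
  if (config$alpha <= 0 || config$alpha > 1) stop("alpha outside (0, 1]")
  config
}

#' Run the full analysis pipeline
#'
#' Stages, in order: panel load + filter, cohort ingestion (VCFs +
#' clinical), patient-graph construction and community detection, cluster
#' annotation (gene/drug exclusivity, drug proportions), per-cluster
#' enrichment, cluster x treatment odds-ratio association, and per-patient
#' reports. All artifacts are written under `out_dir`; a `manifest.json`
#' records every parameter and seed so a rerun with the same config and
#' inputs is byte-identical. A modularity below 0.05 produces a warning
#' (strong patient similarity), not an error.
#'
#' @param config Run config list or YAML path; see
#'   [validate_run_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] started")
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message("[", name, "] done in ",
            format(round(as.numeric(Sys.time() - t0, units = "secs"), 2)), "s")
    res
  }

  panel <- stage("panel", {
    filt <- filter_panel(load_panel(config$panel))
    write_panel(filt$manifest, file.path(out, "panel_filtered.tsv"))
    jsonlite::write_json(filt$report, file.path(out, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    filt$manifest
  })

  ingest <- stage("ingest", {
    gm <- read_cohort_vcf(config$vcfs, panel, coding = config$genotype_coding)
    clinical <- read_clinical(config$clinical)
    write_genotype_matrix(gm, file.path(out, "genotype_matrix.tsv"))
    jsonlite::write_json(qc_summary(gm, panel), file.path(out, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_tsv(summarize_clinical(clinical),
                     file.path(out, "clinical_summary.tsv"), progress = FALSE)
    list(gm = gm, clinical = clinical)
  })

  clustering <- stage("cluster", {
    graph <- build_patient_graph(ingest$gm, metric = config$metric,
                                 edge_threshold = config$edge_threshold)
    readr::write_tsv(graph$edges, file.path(out, "graph_edges.tsv"),
                     progress = FALSE)
    cl <- detect_communities(graph, seed = config$seed,
                             resolution = config$resolution)
    if (!is.na(cl$Q) && cl$Q < 0.05) {
      warning("low modularity (Q = ", format(cl$Q, digits = 3),
              "): clusters stem from strong overall patient similarity")
    }
    write_clustering(cl, file.path(out, "partition.tsv"))
    cl
  })

  annotation <- stage("annotate", {
    ann <- annotate_clusters(clustering, ingest$gm, panel)
    prop <- drug_cluster_proportions(ann)
    gx <- gene_exclusivity(ann)
    dx <- drug_exclusivity(prop)
    readr::write_tsv(tibble::as_tibble(prop, rownames = "drug"),
                     file.path(out, "drug_proportions.tsv"), progress = FALSE)
    jsonlite::write_json(list(gene_exclusivity = gx, drug_exclusivity = dx),
                         file.path(out, "venn_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(ann = ann, prop = prop)
  })

  stage("enrich", {
    map <- read_gmt(config$gmt)
    gene_sets <- lapply(annotation$ann$clusters, `[[`, "genes")
    enr <- enrich_clusters(gene_sets, map, alpha = config$alpha)
    readr::write_tsv(enr, file.path(out, "enrichment.tsv"), progress = FALSE)
    enr
  })

  assoc <- stage("associate", {
    rows <- associate_all(ingest$clinical, clustering,
                          convention = config$convention, z = config$z)
    format_association(rows, file.path(out, "associations.tsv"))
    jsonlite::write_json(rows, file.path(out, "associations.json"),
                         auto_unbox = TRUE, digits = NA)
    rows
  })

  stage("report", {
    dir.create(file.path(out, "reports"), showWarnings = FALSE)
    for (pid in names(clustering$labels)) {
      rep <- render_report(assoc, clustering, pid, proportions = annotation$prop)
      jsonlite::write_json(unclass(rep),
                           file.path(out, "reports", paste0(pid, ".json")),
                           auto_unbox = TRUE, digits = NA)
      writeLines(format_patient_report(rep),
                 file.path(out, "reports", paste0(pid, ".txt")))
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("adrpanel")),
    inputs = list(panel = config$panel, clinical = config$clinical,
                  gmt = config$gmt, n_vcfs = length(config$vcfs)),
    parameters = config[c("metric", "edge_threshold", "resolution", "seed",
                          "convention", "z", "alpha", "genotype_coding")],
    n_clusters = clustering$n_clusters, Q = clustering$Q)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a per-patient susceptibility report
#'
#' Lists the patient's cluster, its drug-proportion profile and the
#' treatments whose odds-ratio point estimate in that cluster exceeds 1
#' (elevated ADR susceptibility). Clusters with fewer than 5 members get
#' a small-cluster caveat. Every report carries a research-use-only
#' banner.
#'
#' @param assoc_rows Output of [associate_all()].
#' @param clustering A `clustering` containing the patient.
#' @param patient_id Patient identifier.
#' @param proportions Optional drug-proportion matrix.
#' @return A `patient_report` list.
#' @export
render_report <- function(assoc_rows, clustering, patient_id, proportions = NULL) {
  if (!patient_id %in% names(clustering$labels)) {
    stop("unknown patient id: ", patient_id)
  }
  cl <- unname(clustering$labels[patient_id])
  cl_size <- sum(clustering$labels == cl)
  rows <- assoc_rows[assoc_rows$cluster == cl, , drop = FALSE]
  flagged <- rows[rows$or > 1, , drop = FALSE]
  profile <- if (!is.null(proportions) && as.character(cl) %in% colnames(proportions)) {
    p <- proportions[, as.character(cl)]
    as.list(p[p > 0])
  } else NULL
  structure(list(
    banner = REPORT_BANNER,
    patient_id = patient_id,
    cluster = cl,
    cluster_size = cl_size,
    small_cluster_caveat = if (cl_size < 5)
      paste0("Cluster has only ", cl_size,
             " member(s); associations are not interpretable.") else NULL,
    drug_profile = profile,
    elevated_risk_treatments = flagged$treatment,
    associations = rows), class = "patient_report")
}

#' Human-readable patient report text
#' @param report A `patient_report`.
#' @return Character vector of lines.
#' @export
format_patient_report <- function(report) {
  lines <- c(
    paste0("== Patient ", report$patient_id, " =="),
    report$banner,
    sprintf("Assigned cluster: %d (%d member(s))", report$cluster,
            report$cluster_size))
  if (!is.null(report$small_cluster_caveat)) {
    lines <- c(lines, paste0("CAVEAT: ", report$small_cluster_caveat))
  }
  if (length(report$elevated_risk_treatments) > 0) {
    lines <- c(lines, "Treatments with elevated ADR susceptibility (OR > 1):",
               paste0("  - ", report$elevated_risk_treatments))
  } else {
    lines <- c(lines, "No treatment shows an elevated odds ratio in this cluster.")
  }
  lines
}
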