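# Panel manifest: the curated SNP multipanel with gene / drug / toxicity
# annotations and design-exclusion flags.

PANEL_CATEGORIES <- c("transporter", "phase_I_metabolism", "phase_II_metabolism",
                      "dna_repair", "other_target_signaling")

PANEL_COLUMNS <- c("rsid", "chrom", "pos", "ref", "alt", "gene", "category",
                   "drug_annotations", "radiotoxicity", "design_excluded",
                   "duplicate_of")

new_panel_manifest <- function(variants, provenance = character(0)) {
  structure(variants, class = c("panel_manifest", class(tibble::tibble())),
            provenance = provenance)
}

#' Load a panel manifest from TSV
#'
#' The manifest is a UTF-8 TSV with one row per panel variant and mandatory
#' columns `rsid`, `chrom`, `pos` (1-based, hg19), `ref`, `alt`, `gene`
#' (empty for intergenic), `category` (one of transporter,
#' phase_I_metabolism, phase_II_metabolism, dna_repair,
#' other_target_signaling), `drug_annotations` (semicolon-separated
#' `drug|phenotype_category` pairs), `radiotoxicity`, `design_excluded`
#' (logicals) and `duplicate_of` (rsid of the earlier copy, or empty).
#'
#' All row-level violations (non-positive position, unknown category,
#' `duplicate_of` naming a missing or identical rsid) are collected and
#' reported together in a single error.
#'
#' @param path Path to the TSV file.
#' @return A `panel_manifest` (a tibble subclass) in file order.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel manifest not found: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(PANEL_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("panel manifest format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  pos_num <- suppressWarnings(as.numeric(raw$pos))
  bad_pos <- which(is.na(pos_num) | pos_num != floor(pos_num))
  if (length(bad_pos) > 0) {
    stop("panel manifest row error: malformed position at line(s) ",
         paste(bad_pos + 1, collapse = ", "), " (rsid ",
         paste(raw$rsid[bad_pos], collapse = ", "), ")")
  }
  man <- tibble::tibble(
    rsid = raw$rsid,
    chrom = raw$chrom,
    pos = as.integer(pos_num),
    ref = raw$ref,
    alt = raw$alt,
    gene = ifelse(is.na(raw$gene), "", raw$gene),
    category = raw$category,
    drug_annotations = ifelse(is.na(raw$drug_annotations), "", raw$drug_annotations),
    radiotoxicity = as.logical(raw$radiotoxicity),
    design_excluded = as.logical(raw$design_excluded),
    duplicate_of = ifelse(is.na(raw$duplicate_of) | !nzchar(raw$duplicate_of),
                          NA_character_, raw$duplicate_of)
  )
  problems <- character(0)
  bad <- which(man$pos < 1)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("pos < 1 for rsid ", man$rsid[bad],
                                   " (line ", bad + 1, ")"))
  }
  bad <- which(!man$category %in% PANEL_CATEGORIES)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("unknown category '", man$category[bad],
                                   "' for rsid ", man$rsid[bad]))
  }
  dup <- which(!is.na(man$duplicate_of))
  bad <- dup[!(man$duplicate_of[dup] %in% man$rsid) |
               man$duplicate_of[dup] == man$rsid[dup]]
  if (length(bad) > 0) {
    problems <- c(problems, paste0("duplicate_of of rsid ", man$rsid[bad],
                                   " does not name a distinct manifest rsid"))
  }
  if (length(problems) > 0) {
    stop("panel manifest row error(s):\n  ", paste(problems, collapse = "\n  "))
  }
  new_panel_manifest(man, provenance = paste0("loaded from ", path))
}

#' Write a panel manifest to TSV
#' @param manifest A `panel_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(manifest, path) {
  out <- tibble::as_tibble(manifest)
  out$duplicate_of <- ifelse(is.na(out$duplicate_of), "", out$duplicate_of)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter a panel manifest to the analyzable variant set
#'
#' Removes variants flagged `design_excluded` (not covered by the assay
#' design) and variants flagged as duplicates of another panel entry
#' (`duplicate_of` set; the first occurrence in file order is kept). A
#' variant flagged both ways is counted once, under `design_excluded`,
#' with a warning.
#'
#' @param manifest A `panel_manifest`.
#' @return A list with `manifest` (the filtered `panel_manifest`) and
#'   `report`: counts `n_input`, `n_design_excluded`, `n_duplicates`,
#'   `n_retained` and `retained_fraction` (a percentage truncated to one
#'   decimal, so 309/326 reports 94.7).
#' @export
filter_panel <- function(manifest) {
  stopifnot(inherits(manifest, "panel_manifest"))
  n_input <- nrow(manifest)
  excl <- isTRUE_vec(manifest$design_excluded)
  dup <- !is.na(manifest$duplicate_of)
  both <- excl & dup
  if (any(both)) {
    warning("variant(s) flagged both design_excluded and duplicate, ",
            "counted under design_excluded: ",
            paste(manifest$rsid[both], collapse = ", "))
  }
  dup_only <- dup & !excl
  keep <- !excl & !dup
  retained <- manifest[keep, ]
  report <- list(
    n_input = n_input,
    n_design_excluded = sum(excl),
    n_duplicates = sum(dup_only),
    n_retained = sum(keep),
    retained_fraction = if (n_input > 0) trunc_pct(sum(keep), n_input, 1) else NA_real_
  )
  list(manifest = new_panel_manifest(retained, attr(manifest, "provenance")),
       report = report)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Gene counts per panel category
#'
#' Counts each gene once, under the category of its first panel occurrence.
#' Intergenic variants (empty `gene`) are reported separately as
#' `intergenic_variants`.
#'
#' @param manifest A (typically filtered) `panel_manifest`.
#' @return Named list: one count per category plus `n_genes` and
#'   `intergenic_variants`.
#' @export
gene_category_summary <- function(manifest) {
  stopifnot(inherits(manifest, "panel_manifest"))
  genic <- manifest[nzchar(manifest$gene), , drop = FALSE]
  first <- genic[!duplicated(genic$gene), , drop = FALSE]
  counts <- vapply(PANEL_CATEGORIES, function(cat) sum(first$category == cat),
                   integer(1))
  c(as.list(counts),
    list(n_genes = nrow(first),
         intergenic_variants = sum(!nzchar(manifest$gene))))
}

#' Tidy drug annotations of a panel
#'
#' Expands the serialized `drug|phenotype_category` pairs into one row per
#' (variant, drug, phenotype) annotation. Drug names are normalized to
#' lower case and combination regimens (separated by `/` or `+`) are
#' expanded into their constituents. Repeated (variant, drug) pairs are
#' collapsed to a single occurrence.
#'
#' @param manifest A `panel_manifest`.
#' @param phenotype_filter If non-NULL, keep only annotations whose
#'   phenotype category matches (default "Toxicity" selects the severe
#'   side-effect annotations; pass NULL to keep all).
#' @return Tibble with columns `rsid`, `gene`, `drug`, `phenotype_category`.
#' @export
panel_drug_annotations <- function(manifest, phenotype_filter = "Toxicity") {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    pairs <- split_semi(manifest$drug_annotations[i])
    if (length(pairs) == 0) return(NULL)
    parts <- strsplit(pairs, "|", fixed = TRUE)
    tibble::tibble(
      rsid = manifest$rsid[i],
      gene = manifest$gene[i],
      drug = vapply(parts, `[`, character(1), 1),
      phenotype_category = vapply(parts, function(p) {
        if (length(p) >= 2) p[2] else ""
      }, character(1))
    )
  })
  ann <- dplyr::bind_rows(rows)
  if (nrow(ann) == 0) {
    return(tibble::tibble(rsid = character(0), gene = character(0),
                          drug = character(0), phenotype_category = character(0)))
  }
  if (!is.null(phenotype_filter)) {
    ann <- ann[ann$phenotype_category %in% phenotype_filter, , drop = FALSE]
  }
  # expand combination regimens, normalize to lower-case generic names
  expanded <- lapply(seq_len(nrow(ann)), function(i) {
    drugs <- tolower(trimws(strsplit(ann$drug[i], "[/+]")[[1]]))
    drugs <- drugs[nzchar(drugs)]
    tibble::tibble(rsid = ann$rsid[i], gene = ann$gene[i], drug = drugs,
                   phenotype_category = ann$phenotype_category[i])
  })
  out <- dplyr::bind_rows(expanded)
  out[!duplicated(out[c("rsid", "drug")]), , drop = FALSE]
}
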