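# Cohort ingestion: per-patient VCFs -> binary carrier matrix; clinical
# table I/O and Table-1-style summaries.

ADR_CATEGORIES <- c("hematologic", "gastrointestinal", "asthenia", "skin",
                    "pain", "dyspnea")

new_genotype_matrix <- function(carrier, missing_mask, coding = "carrier") {
  stopifnot(identical(dim(carrier), dim(missing_mask)))
  structure(list(patient_ids = rownames(carrier),
                 variant_ids = colnames(carrier),
                 carrier = carrier,
                 missing_mask = missing_mask,
                 coding = coding),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$patient_ids), " patients x ",
      length(x$variant_ids), " variants (", x$coding, " coding), ",
      sum(x$missing_mask), " missing calls\n", sep = "")
  invisible(x)
}

#' Read per-patient VCFs into a carrier matrix
#'
#' Each VCF contributes one sample (single-sample files; the sample name
#' defaults to the file stem). Records are matched against the panel by
#' rsid, or failing that by (chrom, pos, ref, alt); multi-allelic ALT
#' fields are decomposed and only the panel's alt allele is matched.
#' Genotypes 0/1 and 1/1 set carrier = 1 (dominant, "carrier" coding) or
#' the alternate-allele dose 1 / 2 under "additive" coding; 0/0 sets 0;
#' missing calls (./.) and panel sites absent from the VCF set carrier = 0
#' with `missing_mask` = 1. Variants present in a VCF but absent from the
#' panel are ignored.
#'
#' @param paths Character vector of VCF paths (plain or bgzipped).
#' @param panel A filtered `panel_manifest`; its row order fixes the
#'   column order of the matrix.
#' @param coding "carrier" (default) or "additive".
#' @param missing_flag_threshold Patients with a larger fraction of
#'   missing panel sites are reported in the `flagged_patients` attribute.
#' @return A `genotype_matrix` with rows in `paths` order and columns in
#'   panel order.
#' @export
read_cohort_vcf <- function(paths, panel, coding = c("carrier", "additive"),
                            missing_flag_threshold = 0.2) {
  coding <- match.arg(coding)
  stopifnot(inherits(panel, "panel_manifest"), length(paths) >= 1)
  n_var <- nrow(panel)
  panel_key <- paste(panel$chrom, panel$pos, panel$ref, panel$alt, sep = ":")

  sample_names <- character(0)
  rows <- list()
  miss <- list()
  for (path in paths) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    sample <- if (ncol(v@gt) >= 2) colnames(v@gt)[2] else NA_character_
    if (is.na(sample) || sample %in% c("", "unknown")) {
      sample <- sub("\\.vcf(\\.gz)?$", "", basename(path))
    }
    if (sample %in% sample_names) stop("duplicate sample name: ", sample)
    sample_names <- c(sample_names, sample)

    carrier_row <- integer(n_var)
    missing_row <- rep(1L, n_var)  # until proven observed
    if (nrow(fix) > 0) {
      gt_first <- as.vector(vcfR::extract.gt(v, element = "GT"))
      for (r in seq_len(nrow(fix))) {
        alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
        gt <- gt_first[r]
        for (ai in seq_along(alts)) {
          key <- paste(fix[r, "CHROM"], fix[r, "POS"], fix[r, "REF"], alts[ai], sep = ":")
          j <- match(fix[r, "ID"], panel$rsid)
          if (is.na(j) || panel_key[j] != key) j <- match(key, panel_key)
          if (is.na(j)) next  # not a panel site
          if (is.na(gt) || grepl("\\.", gt)) {
            carrier_row[j] <- 0L
            missing_row[j] <- 1L
          } else {
            alleles <- as.integer(strsplit(gt, "[/|]")[[1]])
            dose <- sum(alleles == ai)
            carrier_row[j] <- if (coding == "carrier") as.integer(dose > 0) else as.integer(dose)
            missing_row[j] <- 0L
          }
        }
      }
    }
    rows[[sample]] <- carrier_row
    miss[[sample]] <- missing_row
  }
  carrier <- do.call(rbind, rows)
  missing_mask <- do.call(rbind, miss)
  rownames(carrier) <- rownames(missing_mask) <- sample_names
  colnames(carrier) <- colnames(missing_mask) <- panel$rsid
  gm <- new_genotype_matrix(carrier, missing_mask, coding)
  frac_missing <- rowMeans(missing_mask)
  flagged <- sample_names[frac_missing > missing_flag_threshold]
  if (length(flagged) > 0) {
    warning(length(flagged), " patient(s) exceed ", missing_flag_threshold * 100,
            "% missing panel sites: ", paste(flagged, collapse = ", "))
  }
  attr(gm, "flagged_patients") <- flagged
  gm
}

#' Build a genotype matrix directly from a carrier matrix
#'
#' Convenience constructor for simulated or pre-tabulated data.
#' @param carrier Binary (or dose) matrix, patients x variants, with
#'   dimnames.
#' @param missing_mask Optional binary matrix of no-call sites (default
#'   all observed). Missing sites are forced to carrier 0.
#' @param coding Coding label.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(carrier, missing_mask = NULL, coding = "carrier") {
  if (is.null(missing_mask)) {
    missing_mask <- matrix(0L, nrow(carrier), ncol(carrier),
                           dimnames = dimnames(carrier))
  }
  carrier[missing_mask == 1L] <- 0L
  new_genotype_matrix(carrier, missing_mask, coding)
}

#' Write / read a genotype matrix as TSV (bit-exact round trip)
#'
#' Two files are written: `<path>` with the carrier matrix and
#' `<path>.missing` with the missing mask, both patients x variants with a
#' `patient_id` first column.
#' @param gm A `genotype_matrix`.
#' @param path Output TSV path.
#' @return `path` invisibly.
#' @export
write_genotype_matrix <- function(gm, path) {
  to_tbl <- function(m) {
    tibble::as_tibble(as.data.frame(m), rownames = "patient_id")
  }
  readr::write_tsv(to_tbl(gm$carrier), path, progress = FALSE)
  readr::write_tsv(to_tbl(gm$missing_mask), paste0(path, ".missing"), progress = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @param coding Coding label to attach on read.
#' @export
read_genotype_matrix <- function(path, coding = "carrier") {
  from_tbl <- function(p) {
    d <- readr::read_tsv(p, col_types = readr::cols(
      patient_id = readr::col_character(), .default = readr::col_integer()),
      progress = FALSE)
    m <- as.matrix(d[, -1])
    rownames(m) <- d$patient_id
    m
  }
  new_genotype_matrix(from_tbl(path), from_tbl(paste0(path, ".missing")), coding)
}

#' QC summary of observed panel variants
#'
#' A variant is "observed" when at least one patient carries it. Variants
#' are typed SNV vs INDEL by allele lengths and tallied per chromosome.
#'
#' @param gm A `genotype_matrix`.
#' @param panel The `panel_manifest` the matrix was built against.
#' @return List with `n_snv`, `n_indel`, `per_chromosome` (named counts)
#'   and `n_x_chrom`.
#' @export
qc_summary <- function(gm, panel) {
  observed_ids <- gm$variant_ids[colSums(gm$carrier > 0) > 0]
  obs <- panel[panel$rsid %in% observed_ids, , drop = FALSE]
  is_indel <- nchar(obs$ref) != nchar(obs$alt)
  per_chrom <- table(obs$chrom)
  list(n_snv = sum(!is_indel),
       n_indel = sum(is_indel),
       per_chromosome = as.list(per_chrom),
       n_x_chrom = sum(obs$chrom == "X"))
}

#' Read / write the clinical table
#'
#' CSV with columns `patient_id`, `age`, `sex`, `stage`, `treatments`
#' (semicolon-separated subset of cisplatin, carboplatin, pemetrexed,
#' radiotherapy, other), `adr_any` (logical) and `adr_categories`
#' (semicolon-separated subset of hematologic, gastrointestinal, asthenia,
#' skin, pain, dyspnea). `adr_any` must be TRUE whenever `adr_categories`
#' is non-empty.
#'
#' @param path CSV path.
#' @return Tibble, one row per patient.
#' @export
read_clinical <- function(path) {
  clin <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    stage = readr::col_character(),
    treatments = readr::col_character(),
    adr_any = readr::col_logical(),
    adr_categories = readr::col_character()
  ), progress = FALSE)
  clin$treatments[is.na(clin$treatments)] <- ""
  clin$adr_categories[is.na(clin$adr_categories)] <- ""
  validate_clinical(clin)
  clin
}

#' @rdname read_clinical
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(clinical, path, progress = FALSE)
  invisible(path)
}

validate_clinical <- function(clinical) {
  if (anyDuplicated(clinical$patient_id)) stop("duplicate patient ids in clinical table")
  has_cat <- nzchar(clinical$adr_categories)
  if (any(has_cat & !clinical$adr_any)) {
    stop("adr_any must be TRUE when adr_categories is non-empty")
  }
  invisible(clinical)
}

treatments_of <- function(clinical) {
  lapply(clinical$treatments, split_semi)
}

#' Cohort summary in the style of a clinical Table 1
#'
#' Counts and truncated percentages for sex, stage, ADR status, per-category
#' toxicity and treatments (including derived platinum-doublet and
#' non-platinum rows).
#'
#' @param clinical Clinical tibble.
#' @param digits Decimal places of the truncated percentages (default 1).
#' @return Tibble with `group`, `label`, `count`, `pct`, `pct_label`.
#' @export
summarize_clinical <- function(clinical, digits = 1) {
  n <- nrow(clinical)
  if (n == 0) stop("clinical table is empty")
  tx <- treatments_of(clinical)
  has_tx <- function(drugs) vapply(tx, function(t) any(drugs %in% t), logical(1))
  row <- function(group, label, count) {
    tibble::tibble(group = group, label = label, count = count,
                   pct = trunc_pct(count, n, digits),
                   pct_label = format_pct(count, n, digits))
  }
  out <- list(row("cohort", "patients", n))
  for (s in sort(unique(clinical$sex))) {
    out <- c(out, list(row("sex", s, sum(clinical$sex == s))))
  }
  for (s in sort(unique(clinical$stage))) {
    out <- c(out, list(row("stage", s, sum(clinical$stage == s))))
  }
  out <- c(out, list(row("toxicity", "patients_with_adrs", sum(clinical$adr_any))))
  for (cat in ADR_CATEGORIES) {
    cnt <- sum(vapply(clinical$adr_categories,
                      function(x) cat %in% split_semi(x), logical(1)))
    out <- c(out, list(row("toxicity", cat, cnt)))
  }
  single <- c("cisplatin", "carboplatin", "pemetrexed", "radiotherapy", "other")
  for (d in single) out <- c(out, list(row("therapy", d, sum(has_tx(d)))))
  out <- c(out, list(
    row("therapy", "platinum_doublet", sum(has_tx(c("cisplatin", "carboplatin")))),
    row("therapy", "chemotherapy",
        sum(has_tx(c("cisplatin", "carboplatin", "pemetrexed", "other"))))
  ))
  dplyr::bind_rows(out)
}
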