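# Cluster x treatment 2x2 tables, odds ratios with Woolf CIs and the
# Haldane-Anscombe correction, chi-square, and an exhaustive integer-table
# recovery oracle for printed OR/CI pairs.

#' Aggregate treatment definitions
#'
#' Aggregates are unions of member treatments; a patient receiving any
#' member counts once.
#' @export
TREATMENT_AGGREGATES <- list(
  platinum_compounds = c("cisplatin", "carboplatin"),
  carbo_pem = c("carboplatin", "pemetrexed"),
  radio_platinum = c("radiotherapy", "cisplatin", "carboplatin")
)

expand_treatment <- function(treatment) {
  TREATMENT_AGGREGATES[[treatment]] %||% treatment
}

new_contingency <- function(a, b, c, d, convention = "A",
                            treatment = NA_character_, cluster = NA_integer_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), convention = convention,
                 treatment = treatment, cluster = cluster),
            class = "contingency_table")
}

#' Construct a 2x2 contingency table
#' @param a,b,c,d Non-negative integer cells. Rows are the exposure
#'   (convention A: in-cluster vs out-of-cluster among treated patients),
#'   columns are (ADR, no ADR).
#' @param convention Orientation note ("A" or "B").
#' @param treatment,cluster Optional labels.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, convention = "A",
                              treatment = NA_character_, cluster = NA_integer_) {
  new_contingency(a, b, c, d, convention, treatment, cluster)
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(exposure = c("exposed", "unexposed"),
                              outcome = c("ADR", "no ADR")))
  cat("<contingency_table> convention ", x$convention, "\n", sep = "")
  print(m)
  invisible(x)
}

#' Build a cluster x treatment 2x2 table against ADR outcome
#'
#' Convention A (default): among patients receiving the treatment, rows
#' are (in cluster, not in cluster) and columns (ADR, no ADR). Convention
#' B: within the cluster, rows are (treated, untreated).
#'
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param clustering A `clustering` covering the clinical patients.
#' @param treatment Treatment label; aggregate names
#'   (`platinum_compounds`, `carbo_pem`, `radio_platinum`) expand to the
#'   union of their members.
#' @param cluster Cluster index.
#' @param convention "A" or "B".
#' @return A `contingency_table`.
#' @export
build_contingency <- function(clinical, clustering, treatment, cluster,
                              convention = c("A", "B")) {
  convention <- match.arg(convention)
  if (!all(clinical$patient_id %in% names(clustering$labels))) {
    stop("clustering labels must cover all clinical patients")
  }
  drugs <- expand_treatment(treatment)
  treated <- vapply(clinical$treatments,
                    function(x) any(drugs %in% split_semi(x)), logical(1))
  if (!any(treated)) stop("no patients received treatment '", treatment, "'")
  in_cluster <- clustering$labels[clinical$patient_id] == cluster
  adr <- clinical$adr_any
  if (convention == "A") {
    sel <- treated
    exposed <- in_cluster[sel]
  } else {
    sel <- in_cluster
    exposed <- treated[sel]
  }
  adr_sel <- adr[sel]
  new_contingency(sum(exposed & adr_sel), sum(exposed & !adr_sel),
                  sum(!exposed & adr_sel), sum(!exposed & !adr_sel),
                  convention, treatment, cluster)
}

#' Odds ratio with Woolf 95% CI and chi-square
#'
#' If any cell is zero, 0.5 is added to ALL four cells (Haldane-Anscombe)
#' before computing OR = ad/bc and SE(ln OR) = sqrt(1/a + 1/b + 1/c +
#' 1/d); the CI is exp(ln OR +/- z * SE). The Pearson chi-square (Yates
#' correction optional, off by default) is computed on the raw cells and
#' is NA when a raw margin is zero.
#'
#' @param table A `contingency_table` (or a list/vector with a, b, c, d).
#' @param z Normal quantile for the 95% CI. The default 1.96 is the
#'   conventional two-decimal quantile; it reproduces published
#'   MedCalc-style interval bounds, which the full-precision quantile
#'   1.959964 does not always do.
#' @param haldane Apply the zero-cell correction (default TRUE). With
#'   `haldane = FALSE` a zero cell is an error.
#' @param yates Apply Yates continuity correction to the chi-square.
#' @return An `or_estimate`: list with `or_value`, `ci_low`, `ci_high`,
#'   `se_log`, `z`, `haldane_applied`, `chi2`, `p_chi2` and the raw cells.
#' @export
odds_ratio <- function(table, z = 1.96, haldane = TRUE, yates = FALSE) {
  if (!inherits(table, "contingency_table")) {
    table <- do.call(new_contingency, as.list(stats::setNames(
      as.numeric(unlist(table)[1:4]), c("a", "b", "c", "d"))))
  }
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  zero <- any(c(a, b, c, d) == 0)
  if (zero && !haldane) stop("zero cell with haldane = FALSE")
  shift <- if (zero) 0.5 else 0
  a2 <- a + shift; b2 <- b + shift; c2 <- c + shift; d2 <- d + shift
  if (any(c(a2 + b2, c2 + d2, a2 + c2, b2 + d2) == 0)) {
    stop("a row or column sums to zero even after correction")
  }
  or <- a2 * d2 / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  raw <- matrix(c(a, c, b, d), 2, 2)
  chi <- if (any(rowSums(raw) == 0) || any(colSums(raw) == 0)) {
    list(statistic = NA_real_, p.value = NA_real_)
  } else {
    suppressWarnings(stats::chisq.test(raw, correct = yates))
  }
  structure(list(or_value = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 se_log = se, z = z, haldane_applied = zero,
                 chi2 = unname(chi$statistic), p_chi2 = unname(chi$p.value),
                 table = table),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f)%s; chi2 %s, p %s\n",
              round_half_up(x$or_value), round_half_up(x$ci_low),
              round_half_up(x$ci_high),
              if (x$haldane_applied) " [Haldane +0.5]" else "",
              format(x$chi2, digits = 3), format(x$p_chi2, digits = 3)))
  invisible(x)
}

# vectorized OR/CI over integer cell vectors (internal; used by the
# recovery oracle and coverage simulations)
or_ci_vec <- function(a, b, c, d, z = 1.96) {
  zero <- (a == 0 | b == 0 | c == 0 | d == 0)
  a2 <- a + 0.5 * zero; b2 <- b + 0.5 * zero
  c2 <- c + 0.5 * zero; d2 <- d + 0.5 * zero
  or <- a2 * d2 / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  list(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se))
}

enumerate_tables <- function(n_max, total_exact = FALSE) {
  g <- expand.grid(a = 0:n_max, b = 0:n_max, c = 0:n_max)
  g <- g[g$a + g$b + g$c <= n_max, , drop = FALSE]
  if (total_exact) {
    d <- n_max - (g$a + g$b + g$c)
    out <- data.frame(a = g$a, b = g$b, c = g$c, d = d)
  } else {
    dmax <- n_max - (g$a + g$b + g$c)
    idx <- rep.int(seq_len(nrow(g)), dmax + 1)
    out <- data.frame(a = g$a[idx], b = g$b[idx], c = g$c[idx],
                      d = sequence(dmax + 1) - 1L)
  }
  out
}

#' Recover integer 2x2 tables from a printed OR/CI pair
#'
#' Exhaustively enumerates all integer tables with total at most (or
#' exactly) `n_max`, computes each table's Woolf CI under the package's
#' odds-ratio rules, and returns every table whose bounds round
#' (half-up) to the printed interval. An empty result is valid; targets
#' with the OR outside its own CI can match nothing.
#'
#' @param or_target Printed odds ratio (used for reporting; matching is on
#'   the CI bounds, which pin the OR through the Woolf geometric-mean
#'   identity).
#' @param ci_target Length-2 numeric, printed (low, high).
#' @param n_max Total-count bound (<= a few hundred is practical).
#' @param decimals Printed precision (default 2).
#' @param z Normal quantile (default 1.96).
#' @param total_exact If TRUE, only tables with total exactly `n_max`.
#' @return Tibble with columns `a`, `b`, `c`, `d`, `total`, `or`,
#'   `ci_low`, `ci_high` (rounded at `decimals`).
#' @export
recover_table <- function(or_target, ci_target, n_max, decimals = 2,
                          z = 1.96, total_exact = FALSE) {
  stopifnot(length(ci_target) == 2, n_max >= 1)
  tabs <- enumerate_tables(n_max, total_exact)
  r <- or_ci_vec(tabs$a, tabs$b, tabs$c, tabs$d, z)
  hit <- round_half_up(r$lo, decimals) == ci_target[1] &
         round_half_up(r$hi, decimals) == ci_target[2]
  hit[is.na(hit)] <- FALSE
  out <- tibble::tibble(a = tabs$a[hit], b = tabs$b[hit], c = tabs$c[hit],
                        d = tabs$d[hit],
                        total = tabs$a[hit] + tabs$b[hit] + tabs$c[hit] + tabs$d[hit],
                        or = round_half_up(r$or[hit], decimals),
                        ci_low = round_half_up(r$lo[hit], decimals),
                        ci_high = round_half_up(r$hi[hit], decimals))
  out[order(out$total, out$a, out$b, out$c, out$d), ]
}

#' Odds-ratio association across all treatments and clusters
#'
#' One row per (treatment, cluster) pair; rows whose table cannot be
#' built (for example a treatment nobody received) are skipped with a
#' warning. The `risk` flag marks OR > 1 (elevated ADR susceptibility for
#' cluster members under that treatment).
#'
#' @param clinical Clinical tibble.
#' @param clustering A `clustering`.
#' @param treatments Character vector of treatments; defaults to the
#'   individual treatments observed in the table plus the three aggregates
#'   (`platinum_compounds`, `carbo_pem`, `radio_platinum`).
#' @param convention,z,haldane Passed to [build_contingency()] /
#'   [odds_ratio()].
#' @return Tibble with treatment, cluster, cells, OR, CI, chi-square and
#'   risk flag.
#' @export
associate_all <- function(clinical, clustering, treatments = NULL,
                          convention = "A", z = 1.96, haldane = TRUE) {
  if (is.null(treatments)) {
    observed <- sort(unique(unlist(lapply(clinical$treatments, split_semi))))
    observed <- setdiff(observed, "other")
    treatments <- c(observed, names(TREATMENT_AGGREGATES))
  }
  clusters <- sort(unique(unname(clustering$labels)))
  rows <- list()
  for (tr in treatments) {
    for (cl in clusters) {
      tab <- tryCatch(build_contingency(clinical, clustering, tr, cl, convention),
                      error = function(e) {
                        warning("skipping ", tr, " x cluster ", cl, ": ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(tab)) next
      est <- odds_ratio(tab, z = z, haldane = haldane)
      rows[[length(rows) + 1]] <- tibble::tibble(
        treatment = tr, cluster = cl,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        or = est$or_value, ci_low = est$ci_low, ci_high = est$ci_high,
        chi2 = est$chi2, p_chi2 = est$p_chi2,
        haldane = est$haldane_applied, risk = est$or_value > 1)
    }
  }
  dplyr::bind_rows(rows)
}

#' Serialize association rows for report display
#'
#' Rounds OR and CI bounds half-up to two decimals (display convention;
#' internal values keep full precision).
#' @param rows Output of [associate_all()].
#' @param path Optional TSV output path.
#' @return The rounded tibble (invisibly if written).
#' @export
format_association <- function(rows, path = NULL) {
  out <- rows
  for (col in c("or", "ci_low", "ci_high")) out[[col]] <- round_half_up(out[[col]])
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
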