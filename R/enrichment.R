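# Hypergeometric over-representation of term -> gene sets per cluster,
# with Benjamini-Hochberg FDR within each cluster.

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of at least k
#' query hits in a term of size K when drawing n genes from a universe of
#' N without replacement. Computed in log space via [stats::phyper()].
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Term size.
#' @param n Query size.
#' @param N Universe size (K, n <= N).
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    stop("inconsistent hypergeometric counts")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order
#' matches input order.
#'
#' @param p Vector of p-values in (0, 1].
#' @return q-values in input order (empty input gives empty output).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Read a GMT gene-set file into a term map
#'
#' @param path GMT path (term id, description, tab-separated member genes).
#' @param namespace_path Optional two-column TSV (`term`, `namespace`, BP
#'   or MF); terms absent from the table get namespace NA.
#' @param universe Optional background gene set; defaults to the union of
#'   all term genes.
#' @return A `term_gene_map`: list with `terms` (named list of gene
#'   vectors), `names` (term descriptions), `namespace`, `universe`.
#' @export
read_gmt <- function(path, namespace_path = NULL, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  desc <- vapply(strsplit(readLines(path), "\t"), `[`, character(1), 2)
  names(desc) <- names(sets)
  ns <- stats::setNames(rep(NA_character_, length(sets)), names(sets))
  if (!is.null(namespace_path)) {
    tab <- readr::read_tsv(namespace_path, col_types = "cc", progress = FALSE)
    ns[tab$term] <- tab$namespace
  }
  term_gene_map(sets, universe = universe, names = desc, namespace = ns)
}

#' Construct a term map from R objects
#' @param terms Named list of gene character vectors.
#' @param universe Background gene set (default: union of term genes).
#' @param names,namespace Optional named metadata vectors.
#' @return A `term_gene_map`.
#' @export
term_gene_map <- function(terms, universe = NULL, names = NULL, namespace = NULL) {
  universe <- universe %||% unique(unlist(terms))
  outside <- setdiff(unique(unlist(terms)), universe)
  if (length(outside) > 0) {
    stop("term genes outside the universe: ", paste(utils::head(outside, 5), collapse = ", "))
  }
  structure(list(terms = terms, names = names, namespace = namespace,
                 universe = universe),
            class = "term_gene_map")
}

#' Write a term map to GMT
#' @param map A `term_gene_map`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_gmt <- function(map, path) {
  lines <- vapply(names(map$terms), function(t) {
    desc <- if (!is.null(map$names) && !is.na(map$names[t] %||% NA)) map$names[t] else t
    paste(c(t, desc, map$terms[[t]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-cluster hypergeometric over-representation
#'
#' One upper-tail hypergeometric test per (cluster, term) for terms with
#' `min_term_size <= K <= max_term_size`; BH adjustment applied within
#' each cluster. Query genes outside the universe are dropped with a
#' warning.
#'
#' @param gene_sets Named list of per-cluster gene vectors.
#' @param map A `term_gene_map`.
#' @param alpha FDR level used for the `significant` flag (default 0.05).
#' @param min_term_size,max_term_size Term-size window (defaults 3, 500).
#' @return Tibble with columns `cluster`, `term`, `namespace`, `k`, `K`,
#'   `n`, `N`, `p`, `q`, `significant`, sorted by cluster then q then p.
#' @export
enrich_clusters <- function(gene_sets, map, alpha = 0.05,
                            min_term_size = 3, max_term_size = 500) {
  stopifnot(inherits(map, "term_gene_map"))
  N <- length(map$universe)
  if (N == 0) stop("empty universe")
  term_sizes <- vapply(map$terms, length, integer(1))
  terms <- names(map$terms)[term_sizes >= min_term_size & term_sizes <= max_term_size]
  out <- list()
  for (cl in names(gene_sets)) {
    genes <- unique(gene_sets[[cl]])
    dropped <- setdiff(genes, map$universe)
    if (length(dropped) > 0) {
      warning("cluster ", cl, ": ", length(dropped),
              " gene(s) outside the universe dropped")
    }
    query <- intersect(genes, map$universe)
    n <- length(query)
    if (n == 0 || length(terms) == 0) next
    k <- vapply(terms, function(t) length(intersect(query, map$terms[[t]])), integer(1))
    K <- term_sizes[terms]
    p <- hypergeom_upper_tail(k, K, n, N)
    q <- bh_adjust(p)
    ns <- if (!is.null(map$namespace)) unname(map$namespace[terms]) else NA_character_
    res <- tibble::tibble(cluster = cl, term = terms, namespace = ns,
                          k = unname(k), K = unname(K), n = n, N = N,
                          p = unname(p), q = unname(q),
                          significant = unname(q) <= alpha)
    out[[cl]] <- res[order(res$q, res$p), ]
  }
  if (length(out) == 0) {
    return(tibble::tibble(cluster = character(0), term = character(0),
                          namespace = character(0), k = integer(0), K = integer(0),
                          n = integer(0), N = integer(0), p = numeric(0),
                          q = numeric(0), significant = logical(0)))
  }
  dplyr::bind_rows(out)
}
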