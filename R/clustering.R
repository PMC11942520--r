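# Patient-similarity network and deterministic greedy-modularity
# (Louvain-style) community detection.

#' Build a patient-similarity graph from a carrier matrix
#'
#' Pairwise similarity between patients' binary carrier profiles:
#' * `jaccard`: |intersection| / |union| (default);
#' * `dice`: 2|intersection| / (|A| + |B|);
#' * `hamming_similarity`: fraction of panel sites with equal status.
#' Two empty carrier sets have Jaccard/Dice similarity defined as 0 (with a
#' warning). Edges with weight below `edge_threshold` are dropped; isolated
#' nodes are permitted and later become singleton communities.
#'
#' The default threshold 0.2 is chosen for carrier profiles with a block
#' structure: it sits far above the similarity expected between patients
#' sharing only background variants (about 0.05-0.1) and well below the
#' similarity of patients sharing a variant block (0.3+). On a complete
#' weighted graph (threshold 0) modularity optimisation cannot keep very
#' small communities separate (resolution limit), so thresholding is what
#' makes single-patient clusters detectable.
#'
#' @param gm A `genotype_matrix`.
#' @param metric One of "jaccard", "dice", "hamming_similarity".
#' @param edge_threshold Minimum retained edge weight in \[0, 1\].
#' @return A `patient_graph`: list with `nodes`, `edges` (tibble `from`,
#'   `to`, `weight`, with `from` < `to`), `similarity_metric`,
#'   `edge_threshold`.
#' @export
build_patient_graph <- function(gm, metric = c("jaccard", "dice", "hamming_similarity"),
                                edge_threshold = 0.2) {
  metric <- match.arg(metric)
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- gm$carrier > 0
  storage.mode(m) <- "numeric"
  if (nrow(m) < 2) stop("need at least 2 patients")
  if (ncol(m) < 1) stop("need at least 1 variant column")
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  n_var <- ncol(m)
  sz_i <- matrix(sizes, nrow(m), nrow(m))
  sz_j <- t(sz_i)
  sim <- switch(metric,
    jaccard = {
      uni <- sz_i + sz_j - inter
      s <- ifelse(uni == 0, 0, inter / uni)
      if (any(uni == 0 & upper.tri(uni))) {
        warning("patient pair(s) with two empty carrier sets: similarity set to 0")
      }
      s
    },
    dice = {
      tot <- sz_i + sz_j
      s <- ifelse(tot == 0, 0, 2 * inter / tot)
      if (any(tot == 0 & upper.tri(tot))) {
        warning("patient pair(s) with two empty carrier sets: similarity set to 0")
      }
      s
    },
    hamming_similarity = 1 - (sz_i + sz_j - 2 * inter) / n_var
  )
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  w <- sim[idx]
  keep <- w >= edge_threshold & w > 0
  edges <- tibble::tibble(
    from = rownames(m)[idx[keep, 1]],
    to = rownames(m)[idx[keep, 2]],
    weight = w[keep]
  )
  structure(list(nodes = rownames(m), edges = edges,
                 similarity_metric = metric, edge_threshold = edge_threshold),
            class = "patient_graph")
}

#' @export
print.patient_graph <- function(x, ...) {
  cat("<patient_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", x$similarity_metric, ", threshold ", x$edge_threshold,
      ")\n", sep = "")
  invisible(x)
}

graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  W <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    W[cbind(i, j)] <- graph$edges$weight
    W[cbind(j, i)] <- graph$edges$weight
  }
  W
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' Q = sum_c (e_cc - gamma * a_c^2), where e_cc is the fraction of total
#' edge weight falling inside community c and a_c the fraction of edge-end
#' weight attached to c.
#'
#' @param graph A `patient_graph`.
#' @param labels Named vector (patient -> community) covering all nodes,
#'   or an unnamed vector in node order.
#' @param resolution Resolution parameter gamma (default 1).
#' @return Modularity Q.
#' @export
graph_modularity <- function(graph, labels, resolution = 1) {
  W <- graph_adjacency(graph)
  lab <- align_labels(graph, labels)
  two_m <- sum(W)
  if (two_m == 0) stop("graph has zero total edge weight")
  q <- 0
  for (c in unique(lab)) {
    members <- which(lab == c)
    e_cc <- sum(W[members, members, drop = FALSE]) / two_m
    a_c <- sum(W[members, , drop = FALSE]) / two_m
    q <- q + (e_cc - resolution * a_c^2)
  }
  q
}

align_labels <- function(graph, labels) {
  if (!is.null(names(labels))) {
    if (!all(graph$nodes %in% names(labels))) stop("labels must cover all nodes")
    labels <- labels[graph$nodes]
  } else if (length(labels) != length(graph$nodes)) {
    stop("labels must cover all nodes")
  }
  as.vector(labels)
}

#' Detect communities by deterministic greedy modularity optimisation
#'
#' Louvain-style two-phase optimisation: local moving over nodes in sorted
#' patient-id order (ties between equally good moves broken toward the
#' lower community index), followed by graph aggregation, repeated until
#' modularity stops improving. The procedure contains no random draws; the
#' `seed` argument is recorded in the result so that runs are fully
#' reproducible records.
#'
#' Returned labels are canonical: communities indexed from 0 by decreasing
#' size, ties by lexicographically smallest member id.
#'
#' @param graph A `patient_graph` with at least one edge.
#' @param seed Integer recorded in the result.
#' @param resolution Resolution parameter gamma (default 1).
#' @return A `clustering`: list with `labels` (named integer vector,
#'   0-based), `Q` (modularity at resolution 1), `n_clusters`, `seed`.
#' @export
detect_communities <- function(graph, seed = 17L, resolution = 1) {
  W <- graph_adjacency(graph)
  n <- nrow(W)
  ord <- order(rownames(W))
  W <- W[ord, ord]
  if (sum(W) == 0) {
    lab <- seq_len(n)  # degenerate graph: singleton partition
  } else {
    lab <- louvain_partition(W, resolution)
  }
  labels <- stats::setNames(lab, rownames(W))
  labels <- canonicalize_labels(labels)
  labels <- labels[graph$nodes]
  q <- if (sum(W) == 0) NA_real_ else graph_modularity(graph, labels)
  structure(list(labels = labels, Q = q,
                 n_clusters = length(unique(labels)), seed = as.integer(seed),
                 resolution = resolution),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat("<clustering> ", length(x$labels), " patients in ", x$n_clusters,
      " clusters, Q = ", format(x$Q, digits = 3), " (seed ", x$seed, ")\n",
      sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

# Core Louvain on a dense symmetric adjacency (diagonal = 2x internal
# weight of aggregated super-nodes; zero on the original graph).
louvain_partition <- function(W, resolution = 1, tol = 1e-12) {
  n_orig <- nrow(W)
  membership <- seq_len(n_orig)  # original node -> current super-node
  repeat {
    lab <- local_move(W, resolution, tol)
    groups <- sort(unique(lab))
    if (length(groups) == nrow(W)) break  # no merge happened
    # aggregate communities into super-nodes
    P <- outer(lab, groups, `==`) * 1
    W <- t(P) %*% W %*% P
    membership <- match(lab[membership], groups)
    if (nrow(W) == 1) break
  }
  membership
}

local_move <- function(W, resolution, tol) {
  n <- nrow(W)
  lab <- seq_len(n)
  two_m <- sum(W)
  k <- rowSums(W)
  tot <- k  # community total degree (each node its own community)
  repeat {
    moved <- FALSE
    for (i in seq_len(n)) {
      cur <- lab[i]
      w_i <- W[i, ]
      w_i[i] <- 0  # self-weight moves with the node; not a link to others
      # links from i to each community
      w_ic <- tapply(w_i, lab, sum)
      comms <- as.integer(names(w_ic))
      tot_c <- vapply(comms, function(c) tot[c], numeric(1))
      tot_c_noi <- tot_c - (comms == cur) * k[i]
      gain <- w_ic - resolution * k[i] * tot_c_noi / two_m
      base <- gain[comms == cur]
      best <- which(gain > base + tol)
      if (length(best) > 0) {
        # strongest gain, ties toward the lower community index
        g <- gain[best]
        cand <- comms[best][g >= max(g) - tol]
        target <- min(cand)
        tot[cur] <- tot[cur] - k[i]
        tot[target] <- tot[target] + k[i]
        lab[i] <- target
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  lab
}

#' Canonicalize community labels
#'
#' Re-index communities 0-based by decreasing size; ties broken by the
#' lexicographically smallest member id.
#'
#' @param labels Named vector patient -> community.
#' @return Named integer vector with contiguous 0-based labels.
#' @export
canonicalize_labels <- function(labels) {
  stopifnot(!is.null(names(labels)))
  comms <- split(names(labels), labels)
  sizes <- vapply(comms, length, integer(1))
  smallest <- vapply(comms, function(m) min(m), character(1))
  ord <- order(-sizes, smallest)
  new_id <- stats::setNames(seq_along(ord) - 1L, names(comms)[ord])
  out <- new_id[as.character(labels)]
  stats::setNames(as.integer(out), names(labels))
}

#' Build a clustering object from known labels
#'
#' Wraps an externally known partition (for example simulation truth or a
#' published cluster assignment) so it can be used wherever a detected
#' `clustering` is expected. Q is left NA unless a graph is supplied.
#'
#' @param labels Named vector patient -> cluster index.
#' @param graph Optional `patient_graph` used to attach modularity.
#' @param seed Optional seed to record.
#' @return A `clustering`.
#' @export
clustering_from_labels <- function(labels, graph = NULL, seed = NA_integer_) {
  stopifnot(!is.null(names(labels)))
  labels <- stats::setNames(as.integer(labels), names(labels))
  q <- if (!is.null(graph)) graph_modularity(graph, labels) else NA_real_
  structure(list(labels = labels, Q = q,
                 n_clusters = length(unique(labels)),
                 seed = as.integer(seed), resolution = 1),
            class = "clustering")
}

#' Repeat community detection across seeds and check stability
#'
#' @param graph A `patient_graph`.
#' @param seeds Integer vector of seeds (length >= 2).
#' @return List with `stable` (TRUE iff all canonicalized partitions are
#'   identical) and `partitions` (list of `clustering` objects).
#' @export
stability_check <- function(graph, seeds) {
  if (length(seeds) < 2) stop("need at least 2 repeats")
  parts <- lapply(seeds, function(s) detect_communities(graph, seed = s))
  ref <- parts[[1]]$labels
  stable <- all(vapply(parts[-1], function(p) identical(p$labels, ref), logical(1)))
  list(stable = stable, partitions = parts)
}

#' Export / import a clustering partition
#' @param clustering A `clustering`.
#' @param path Two-column TSV path (patient, cluster); Q and seed go to
#'   `<path>.json`.
#' @return `path` invisibly.
#' @export
write_clustering <- function(clustering, path) {
  readr::write_tsv(tibble::tibble(patient_id = names(clustering$labels),
                                  cluster = unname(clustering$labels)),
                   path, progress = FALSE)
  jsonlite::write_json(list(Q = clustering$Q, seed = clustering$seed,
                            n_clusters = clustering$n_clusters,
                            resolution = clustering$resolution),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clustering
#' @export
read_clustering <- function(path) {
  d <- readr::read_tsv(path, col_types = "ci", progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(labels = stats::setNames(as.integer(d$cluster), d$patient_id),
                 Q = meta$Q %||% NA_real_, n_clusters = meta$n_clusters,
                 seed = meta$seed, resolution = meta$resolution %||% 1),
            class = "clustering")
}
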