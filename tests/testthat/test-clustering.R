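test_that("pairwise similarities follow the set definitions", {
  ids <- paste0("v", 1:4)
  gm <- carrier_from_sets(list(A = c("v1", "v2"), B = c("v1", "v2"),
                               C = c("v3", "v4"), D = c("v2", "v3")), ids)
  g <- build_patient_graph(gm, edge_threshold = 0)
  w <- function(x, y) {
    e <- g$edges[(g$edges$from == x & g$edges$to == y) |
                 (g$edges$from == y & g$edges$to == x), ]
    if (nrow(e) == 0) 0 else e$weight
  }
  expect_equal(w("A", "B"), 1)        # identical carrier sets
  expect_equal(w("A", "C"), 0)        # disjoint sets: edge dropped
  expect_equal(w("A", "D"), 1 / 3)    # {v1,v2} vs {v2,v3}

  # dice and hamming on the same pairs
  gd <- build_patient_graph(gm, metric = "dice", edge_threshold = 0)
  expect_equal(gd$edges$weight[gd$edges$from == "A" & gd$edges$to == "D"], 0.5)
  gh <- build_patient_graph(gm, metric = "hamming_similarity", edge_threshold = 0)
  expect_equal(gh$edges$weight[gh$edges$from == "A" & gh$edges$to == "B"], 1)
})

test_that("two empty carrier sets get similarity 0 with a warning", {
  gm <- carrier_from_sets(list(A = character(0), B = character(0), C = "v1"),
                          paste0("v", 1:2))
  expect_warning(g <- build_patient_graph(gm, edge_threshold = 0), "empty carrier")
  expect_false(any(g$edges$from == "A" & g$edges$to == "B"))
})

test_that("edges below the threshold are dropped, isolated nodes permitted", {
  ids <- paste0("v", 1:6)
  gm <- carrier_from_sets(list(A = c("v1", "v2"), B = c("v1", "v2"),
                               C = c("v5", "v6")), ids)
  g <- build_patient_graph(gm, edge_threshold = 0.5)
  expect_equal(nrow(g$edges), 1)  # only the A-B edge survives
  expect_true(all(g$edges$weight >= 0.5))
  expect_true("C" %in% g$nodes)
})

test_that("modularity matches hand-computed values", {
  g <- two_clique_graph()
  lab <- stats::setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  expect_equal(graph_modularity(g, lab), 0.5)           # two clean cliques
  expect_equal(graph_modularity(g, stats::setNames(rep(1, 6), letters[1:6])), 0)
  # both cliques merged under one of two labels, other label empty
  expect_equal(graph_modularity(g, stats::setNames(rep(2, 6), letters[1:6])), 0)

  empty <- two_clique_graph()
  empty$edges <- empty$edges[0, ]
  expect_error(graph_modularity(empty, lab), "zero total edge weight")
})

test_that("modularity agrees with igraph on random weighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:5) {
    n <- 10
    nodes <- sprintf("p%02d", 1:n)
    idx <- utils::combn(n, 2)
    keep <- stats::runif(ncol(idx)) < 0.4
    edges <- tibble::tibble(from = nodes[idx[1, keep]], to = nodes[idx[2, keep]],
                            weight = stats::runif(sum(keep)))
    g <- structure(list(nodes = nodes, edges = edges,
                        similarity_metric = "jaccard", edge_threshold = 0),
                   class = "patient_graph")
    if (nrow(edges) == 0) next
    lab <- stats::setNames(sample(1:3, n, replace = TRUE), nodes)
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = nodes)
    expect_equal(graph_modularity(g, lab),
                 igraph::modularity(ig, lab[nodes],
                                    weights = igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
})

test_that("community detection resolves unambiguous structure", {
  cl <- detect_communities(two_clique_graph())
  expect_equal(cl$n_clusters, 2)
  expect_equal(unname(cl$labels[c("a", "b", "c")]), rep(cl$labels[["a"]], 3))
  expect_equal(unname(cl$labels[c("d", "e", "f")]), rep(cl$labels[["d"]], 3))
  expect_equal(cl$Q, 0.5)

  cl2 <- detect_communities(complete_uniform_graph())
  expect_equal(cl2$n_clusters, 1)
})

test_that("labels are canonical: 0-based, contiguous, size-ordered", {
  sim <- simulate_cohort(small_sim_config())
  g <- build_patient_graph(sim$genotypes)
  cl <- detect_communities(g)
  sizes <- as.integer(table(cl$labels))
  expect_equal(sort(unique(unname(cl$labels))), seq_along(sizes) - 1L)
  expect_true(all(diff(as.integer(table(factor(cl$labels,
    levels = sort(unique(cl$labels)))))) <= 0))
})

test_that("detected modularity never falls below the single-cluster baseline", {
  set.seed(5)
  for (rep in 1:5) {
    cfg <- small_sim_config(seed = 100 + rep)
    sim <- simulate_cohort(cfg)
    g <- build_patient_graph(sim$genotypes, edge_threshold = 0)
    cl <- detect_communities(g)
    expect_gte(cl$Q, 0)
  }
})

test_that("community detection is equivariant under patient relabeling", {
  sim <- simulate_cohort(small_sim_config())
  g <- build_patient_graph(sim$genotypes)
  cl <- detect_communities(g)
  # rename patients so their sort order reverses
  new_ids <- stats::setNames(sprintf("Z%03d", rev(seq_along(g$nodes))), g$nodes)
  g2 <- g
  g2$nodes <- unname(new_ids[g$nodes])
  g2$edges$from <- unname(new_ids[g$edges$from])
  g2$edges$to <- unname(new_ids[g$edges$to])
  cl2 <- detect_communities(g2)
  relabeled <- stats::setNames(cl2$labels[unname(new_ids[names(cl$labels)])],
                               names(cl$labels))
  expect_equal(adjusted_rand_index(cl$labels, relabeled), 1)
})

test_that("planted partitions are recovered exactly at both between-cluster levels", {
  skip_if_not_installed("mclust")
  for (between in c(0.05, 0.1)) {
    for (seed in 1:3) {
      cfg <- simulation_config(seed = 200 + seed,
                               between_cluster_carrier_prob = between)
      sim <- simulate_cohort(cfg)
      g <- build_patient_graph(sim$genotypes)
      cl <- detect_communities(g)
      truth <- sim$truth$cluster[names(cl$labels)]
      expect_equal(adjusted_rand_index(cl$labels, truth), 1)
      expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
      expect_equal(cl$n_clusters, 5)
    }
  }
})

test_that("repeated runs are stable across seeds", {
  g <- two_clique_graph()
  st <- stability_check(g, seeds = c(1, 1))
  expect_true(st$stable)
  st2 <- stability_check(g, seeds = 1:5)
  expect_true(st2$stable)
  expect_error(stability_check(g, seeds = 1), "at least 2")

  sim <- simulate_cohort(simulation_config(seed = 300))
  gg <- build_patient_graph(sim$genotypes)
  expect_true(stability_check(gg, seeds = 1:10)$stable)
})

test_that("partitions round-trip through the TSV/JSON export", {
  cl <- detect_communities(two_clique_graph(), seed = 7)
  path <- tempfile(fileext = ".tsv")
  write_clustering(cl, path)
  back <- read_clustering(path)
  expect_identical(back$labels, cl$labels)
  expect_equal(back$Q, cl$Q)
  expect_equal(back$seed, cl$seed)
})

test_that("the in-package ARI matches mclust on random partitions", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (rep in 1:10) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, 5:1), 1)  # same partition, renamed
})
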