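test_that("pairwise Pearson matches hand-computed values", {
  prof <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
                d = c(1, 3, 2, 4))
  s <- pairwise_pearson(prof)
  expect_equal(s["a", "b"], 1)
  expect_equal(s["a", "c"], -1)
  expect_equal(s["a", "d"], 0.8)       # sum(dx dy)/sqrt(sum dx^2 sum dy^2)
  expect_equal(diag(s), rep(1, 4), ignore_attr = TRUE)
  expect_equal(s, t(s))
  # zero-variance profile: similarity 0 to all others, with warning
  expect_warning(s2 <- pairwise_pearson(rbind(a = c(1, 2, 3),
                                              z = c(5, 5, 5))),
                 "zero-variance")
  expect_equal(s2["a", "z"], 0)
  expect_equal(s2["z", "z"], 1)
  expect_error(pairwise_pearson(matrix(1, 2, 1)), "two features")
})

test_that("k-NN graph construction nominates, thresholds and unions", {
  # all similarities below the cutoff: nodes only
  low <- matrix(0.5, 3, 3); diag(low) <- 1
  rownames(low) <- colnames(low) <- c("a", "b", "c")
  g0 <- build_knn_graph(low, k = 2, r_min = 0.77)
  expect_equal(igraph::vcount(g0), 3)
  expect_equal(igraph::ecount(g0), 0)
  # triangle when everything is similar
  hi <- matrix(0.9, 3, 3); diag(hi) <- 1
  rownames(hi) <- colnames(hi) <- c("a", "b", "c")
  g1 <- build_knn_graph(hi, k = 20, r_min = 0.77)
  expect_equal(igraph::ecount(g1), 3)
  # hand-derived top-1 nominations with union symmetrization:
  # a-b 0.9, b-c 0.8, everything else below cutoff, k=1 -> edges {ab, bc}
  s <- matrix(0.5, 4, 4)
  rownames(s) <- colnames(s) <- c("a", "b", "c", "d")
  s["a", "b"] <- s["b", "a"] <- 0.9
  s["b", "c"] <- s["c", "b"] <- 0.8
  diag(s) <- 1
  g2 <- build_knn_graph(s, k = 1, r_min = 0.77)
  el <- igraph::as_edgelist(g2)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  expect_setequal(key, c("a b", "b c"))
  expect_equal(sort(igraph::E(g2)$weight), c(0.8, 0.9))
  # node order invariance of the edge set
  perm <- c("d", "b", "a", "c")
  g3 <- build_knn_graph(s[perm, perm], k = 1, r_min = 0.77)
  el3 <- igraph::as_edgelist(g3)
  expect_setequal(paste(pmin(el3[, 1], el3[, 2]), pmax(el3[, 1], el3[, 2])),
                  key)
})

test_that("single-pass degree pruning removes weakly connected nodes", {
  g <- igraph::make_graph(~ a - b, b - c, c - d)   # path: all degree <= 2
  expect_equal(igraph::vcount(prune_low_degree(g, 3)), 0)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(igraph::vcount(prune_low_degree(k4, 3)), 4)
  iso <- igraph::add_vertices(k4, 1, name = "iso")
  expect_false("iso" %in% igraph::V(prune_low_degree(iso, 3))$name)
})

test_that("MCL clusters cliques and separates components", {
  # one clique: one cluster
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  igraph::E(k4)$weight <- 1
  expect_equal(unname(mcl_cluster(k4)), rep(1L, 4))
  # two disconnected triangles: exactly two clusters
  tri2 <- igraph::make_graph(~ a - b, b - c, a - c, d - e, e - f, d - f)
  igraph::E(tri2)$weight <- 1
  cl <- mcl_cluster(tri2)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[c("a", "b", "c")])), 1)
  expect_equal(length(unique(cl[c("d", "e", "f")])), 1)
  # bridged cliques: clusters match clique membership
  g <- igraph::make_full_graph(4)
  g <- igraph::disjoint_union(g, igraph::make_full_graph(4))
  igraph::V(g)$name <- letters[1:8]
  igraph::E(g)$weight <- 0.95
  g <- igraph::add_edges(g, c(4, 5), weight = 0.77)
  cl2 <- mcl_cluster(g, inflation = 1.6)
  expect_equal(length(unique(cl2)), 2)
  expect_equal(length(unique(cl2[letters[1:4]])), 1)
  expect_equal(length(unique(cl2[letters[5:8]])), 1)
})

test_that("sparse MCL agrees with an independent dense implementation", {
  set.seed(5)
  for (rep in 1:3) {
    n <- 20
    # planted partition: two dense blocks with sparse cross edges
    block <- rep(1:2, each = n / 2)
    p <- ifelse(outer(block, block, "=="), 0.8, 0.08)
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < p[i, j]) adj[i, j] <- adj[j, i] <- runif(1, 0.7, 1)
    }
    keep <- rowSums(adj) > 0
    adj <- adj[keep, keep]
    rownames(adj) <- colnames(adj) <- paste0("n", which(keep))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    got <- mcl_cluster(g)
    ref <- dense_mcl(adj)
    expect_equal(adjusted_rand_index(got[rownames(adj)], ref), 1)
  }
})

test_that("high inflation on disconnected cliques returns the cliques", {
  for (sizes in list(c(3, 4), c(5, 3, 6), c(4, 4, 3, 5))) {
    g <- Reduce(igraph::disjoint_union, lapply(sizes, igraph::make_full_graph))
    igraph::V(g)$name <- paste0("v", seq_len(sum(sizes)))
    igraph::E(g)$weight <- 1
    cl <- mcl_cluster(g, inflation = 8)
    truth <- rep(seq_along(sizes), sizes)
    expect_equal(adjusted_rand_index(unname(cl), truth), 1)
  }
})

test_that("small clusters merge into the strongest-connected neighbour", {
  # 9-node cluster '3' connects to cluster 1 (total weight 5.2) and
  # cluster 2 (3.1): must merge into cluster 1
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 31, name = paste0("v", 1:31))
  assignment <- stats::setNames(c(rep(1L, 11), rep(2L, 11), rep(3L, 9)),
                                paste0("v", 1:31))
  # internal edges so the graph is meaningful
  g <- igraph::add_edges(g, c(1, 2, 12, 13, 23, 24), weight = 1)
  g <- igraph::add_edges(g, c(23, 1, 24, 2), weight = 2.6)     # 3 -> 1: 5.2
  g <- igraph::add_edges(g, c(25, 12, 26, 13), weight = 1.55)  # 3 -> 2: 3.1
  merged <- merge_small_clusters(assignment, g, min_size = 10)
  expect_equal(length(unique(merged)), 2)
  expect_equal(length(unique(merged[paste0("v", c(1:11, 23:31))])), 1)
  # a cluster of exactly 10 is not merged
  a10 <- stats::setNames(c(rep(1L, 12), rep(2L, 10)), paste0("w", 1:22))
  g10 <- igraph::make_empty_graph(directed = FALSE)
  g10 <- igraph::add_vertices(g10, 22, name = paste0("w", 1:22))
  g10 <- igraph::add_edges(g10, c(1, 13), weight = 1)
  m10 <- merge_small_clusters(a10, g10, min_size = 10)
  expect_equal(length(unique(m10)), 2)
  # a small cluster in its own component is retained
  iso <- stats::setNames(c(rep(1L, 12), rep(2L, 3)), paste0("u", 1:15))
  gi <- igraph::make_empty_graph(directed = FALSE)
  gi <- igraph::add_vertices(gi, 15, name = paste0("u", 1:15))
  gi <- igraph::add_edges(gi, c(1, 2, 13, 14), weight = 1)
  mi <- merge_small_clusters(iso, gi, min_size = 10)
  expect_equal(length(unique(mi)), 2)
})

test_that("merging never increases cluster count nor leaves mergeable
           small clusters", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 60
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.08) adj[i, j] <- adj[j, i] <- runif(1, 0.77, 1)
    }
    rownames(adj) <- colnames(adj) <- paste0("x", 1:n)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    cl <- mcl_cluster(g, inflation = 4)
    merged <- merge_small_clusters(cl, g, min_size = 10)
    expect_lte(length(unique(merged)), length(unique(cl)))
    sizes <- table(merged)
    small <- names(sizes)[sizes < 10]
    el <- igraph::as_edgelist(g)
    for (s in small) {
      members <- names(merged)[merged == as.integer(s)]
      external <- xor(el[, 1] %in% members, el[, 2] %in% members)
      expect_false(any(external))
    }
  }
})
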