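#' Drop genes with uniformly low pseudobulk expression
#'
#' Keeps genes whose maximum average expression across stage-cluster
#' columns exceeds `min_max`.
#'
#' @param pb A `pseudobulk_matrix` from [aggregate_by_cluster_stage()].
#' @param min_max Threshold on the per-gene maximum.
#' @return The filtered `pseudobulk_matrix`.
#' @export
filter_low_expression_genes <- function(pb, min_max = 0.2) {
  keep <- apply(pb$profiles, 1, max) > min_max
  if (!any(keep)) stop("no genes exceed the pseudobulk expression cutoff")
  pb$profiles <- pb$profiles[keep, , drop = FALSE]
  pb
}

#' Build the gene coexpression k-NN graph
#'
#' Pearson-correlates gene profiles across stage-cluster columns and
#' applies the same thresholded k-nearest-neighbour construction as the
#' cell graph ([build_knn_graph()]): each gene nominates its `k` most
#' correlated genes, nominations below `r_min` are dropped, and the result
#' is symmetrized by union.
#'
#' @param pb A filtered `pseudobulk_matrix`.
#' @param k Neighbours per gene.
#' @param r_min Minimum Pearson correlation for an edge.
#' @return An undirected weighted `igraph` over the genes.
#' @export
build_gene_knn_graph <- function(pb, k = 4, r_min = 0.7) {
  if (nrow(pb$profiles) < 2) stop("at least two genes required")
  sim <- pairwise_pearson(pb$profiles)
  build_knn_graph(sim, k = k, r_min = r_min)
}

#' Louvain community detection on a weighted graph
#'
#' Multi-level modularity optimization (local moves plus graph
#' aggregation) with a resolution parameter gamma scaling the null-model
#' term; lower gamma yields fewer, larger communities. The sweep order is
#' randomized, so a seed fixes the partition. Isolated nodes come back as
#' singleton communities. The reported modularity is recomputed from the
#' returned assignment at the requested resolution.
#'
#' @param g An undirected `igraph`; the `weight` edge attribute is used if
#'   present.
#' @param resolution Resolution (granularity) gamma.
#' @param seed Optional integer seed.
#' @return A list of class `gene_clustering` with `assignment` (named
#'   integer vector, IDs size-ordered from 1), `modularity` and
#'   `resolution`.
#' @export
louvain_cluster <- function(g, resolution = 0.65, seed = NULL) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  w <- if (igraph::ecount(g) && !is.null(igraph::E(g)$weight))
    igraph::E(g)$weight else NULL
  run <- function() igraph::cluster_louvain(g, weights = w,
                                            resolution = resolution)
  cl <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  memb <- igraph::membership(cl)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  assignment <- relabel_by_size(stats::setNames(as.integer(memb), ids))
  mod <- igraph::modularity(g, assignment, weights = w,
                            resolution = resolution)
  structure(list(assignment = assignment, modularity = mod,
                 resolution = resolution),
            class = "gene_clustering")
}

#' Write a gene-cluster table as TSV
#'
#' @param gc A `gene_clustering`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_clusters <- function(gc, path) {
  df <- data.frame(gene_id = names(gc$assignment),
                   gene_cluster = unname(gc$assignment))
  df <- df[order(df$gene_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean pseudobulk profile of each gene cluster
#'
#' @param pb The `pseudobulk_matrix` the network was built from (after
#'   [filter_low_expression_genes()]).
#' @param gc A `gene_clustering` over its genes.
#' @return Matrix of gene-cluster mean profiles (clusters x stage-cluster
#'   columns).
#' @export
gene_cluster_profiles <- function(pb, gc) {
  genes <- intersect(names(gc$assignment), rownames(pb$profiles))
  grp <- gc$assignment[genes]
  ids <- sort(unique(grp))
  out <- t(sapply(ids, function(cl) {
    colMeans(pb$profiles[genes[grp == cl], , drop = FALSE])
  }))
  rownames(out) <- paste0("GC", ids)
  out
}
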