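#' Pairwise Pearson similarity between entity profiles
#'
#' Correlates the rows of an entity x feature matrix (cells x PC scores, or
#' genes x pseudobulk columns). Zero-variance profiles get similarity 0 to
#' every other entity (with a warning); the diagonal is always 1.
#'
#' @param profiles Numeric entity x feature matrix with >= 2 features.
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
pairwise_pearson <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop("at least two features per entity required")
  sds <- apply(profiles, 1, stats::sd)
  s <- suppressWarnings(stats::cor(t(profiles)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance profile(s); similarity set to 0")
    s[sds == 0, ] <- 0
    s[, sds == 0] <- 0
  }
  diag(s) <- 1
  if (!is.null(rownames(profiles))) {
    dimnames(s) <- list(rownames(profiles), rownames(profiles))
  }
  s
}

#' Build a thresholded k-nearest-neighbour graph
#'
#' Each node nominates its `k` most similar other nodes, keeping only
#' nominations with similarity `>= r_min`; the directed nomination set is
#' symmetrized by union (an edge exists if either endpoint nominates the
#' other). Edge weight is the Pearson similarity. Ties at the k-th
#' neighbour are broken by node order (row index), so output is
#' reproducible. Nodes with no qualifying neighbour remain as isolated
#' vertices.
#'
#' @param sim Symmetric similarity matrix (e.g. from
#'   [pairwise_pearson()]).
#' @param k Number of nearest neighbours each node nominates.
#' @param r_min Minimum similarity for an edge.
#' @return An undirected `igraph` with edge attribute `weight`.
#' @export
build_knn_graph <- function(sim, k = 20, r_min = 0.77) {
  stopifnot(k >= 1, nrow(sim) == ncol(sim))
  n <- nrow(sim)
  ids <- rownames(sim)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    s_i <- sim[i, ]
    s_i[i] <- -Inf
    ord <- order(-s_i, seq_len(n))
    top <- ord[seq_len(min(k, n - 1))]
    top <- top[s_i[top] >= r_min]
    from <- c(from, rep.int(i, length(top)))
    to <- c(to, top)
  }
  # union-symmetrize: keep each unordered pair once
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(a)) {
    g <- igraph::add_edges(g, rbind(a, b), weight = sim[cbind(a, b)])
  }
  g
}

#' Remove poorly connected nodes
#'
#' Deletes, in a single pass, every node whose degree in the input graph is
#' below `min_degree`, together with its incident edges. Degrees are
#' evaluated once on the input graph; the removal is not iterated, so a
#' node kept here may have lower degree in the output.
#'
#' @param g An `igraph`.
#' @param min_degree Minimum degree to be kept.
#' @return The pruned graph.
#' @export
prune_low_degree <- function(g, min_degree = 3) {
  igraph::delete_vertices(g, which(igraph::degree(g) < min_degree))
}

#' Markov Cluster algorithm on a weighted graph
#'
#' Classic MCL: the weighted adjacency matrix is regularized with
#' self-loops (loop weight = the node's maximum incident edge weight, 1
#' for isolated nodes), column-normalized to a stochastic matrix, then
#' iterated through expansion (matrix power), inflation (entrywise power
#' followed by column renormalization) and pruning of entries below
#' `prune` until the matrix changes by less than `tol` or `max_iter` is
#' reached (the latter returns the current clustering with a warning).
#' Clusters are the connected components of the non-zero structure of the
#' limit matrix, so attractor systems that share nodes are merged and
#' disconnected graph components never share a cluster. Cluster IDs are
#' contiguous from 1 in order of decreasing size (ties: smallest member
#' node first).
#'
#' @param g An undirected weighted `igraph`.
#' @param inflation Inflation exponent (granularity; higher = more
#'   clusters).
#' @param expansion Expansion power (integer >= 2).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max absolute matrix change.
#' @param prune Entries below this value are zeroed each iteration.
#' @return Named integer vector mapping node name to cluster ID.
#' @export
mcl_cluster <- function(g, inflation = 1.6, expansion = 2, max_iter = 200,
                        tol = 1e-6, prune = 1e-5) {
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  a <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g)) "weight"
                                   else NULL, sparse = TRUE)
  a <- methods::as(a, "CsparseMatrix") * 1.0
  loop <- apply(a, 2, max)
  loop[loop == 0] <- 1
  diag(a) <- loop
  normalize_cols <- function(m) {
    cs <- Matrix::colSums(m)
    m %*% Matrix::Diagonal(x = 1 / cs)
  }
  m <- normalize_cols(a)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m_new <- m
    for (e in seq_len(expansion - 1)) m_new <- m_new %*% m
    m_new <- methods::as(m_new, "CsparseMatrix")
    m_new@x <- m_new@x^inflation
    m_new <- Matrix::drop0(m_new)
    m_new@x[m_new@x < prune] <- 0
    m_new <- Matrix::drop0(m_new)
    # a fully pruned column would break stochasticity; restore its maximum
    cs <- Matrix::colSums(m_new)
    if (any(cs == 0)) {
      for (j in which(cs == 0)) {
        col <- m[, j]
        m_new[which.max(col), j] <- 1
      }
    }
    m_new <- normalize_cols(m_new)
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter, " iterations")
  }
  supp <- methods::as(Matrix::drop0(m), "TsparseMatrix")
  cluster_graph <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(supp@i)) {
    e <- cbind(supp@i + 1L, supp@j + 1L)
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    if (nrow(e)) cluster_graph <- igraph::add_edges(cluster_graph, t(e))
  }
  comp <- igraph::components(cluster_graph)$membership
  relabel_by_size(stats::setNames(comp, ids))
}

# contiguous cluster IDs from 1, decreasing size, ties by smallest member
relabel_by_size <- function(assignment) {
  nm <- names(assignment)
  sizes <- table(assignment)
  first_member <- tapply(seq_along(assignment), assignment, min)
  ord <- order(-as.vector(sizes[names(first_member)]), first_member)
  new_id <- stats::setNames(seq_along(ord), names(first_member)[ord])
  stats::setNames(as.integer(new_id[as.character(assignment)]), nm)
}

#' Merge small clusters into their best-connected neighbour
#'
#' Processes clusters smaller than `min_size` in ascending size order; each
#' is reassigned wholesale to the neighbouring cluster with the highest sum
#' of edge weights crossing between the two clusters. After every merge,
#' sizes are re-evaluated (a merge may lift a target cluster above the
#' threshold, and a grown small cluster may stop qualifying). Small
#' clusters with no external edges (their own connected component) are
#' left unchanged. Ties in connection weight go to the lower cluster ID.
#'
#' @param assignment Named integer vector node -> cluster ID covering the
#'   nodes of `g`.
#' @param g The weighted `igraph` the clustering refers to.
#' @param min_size Clusters with fewer members are merged.
#' @return Relabelled named integer vector (IDs again size-ordered).
#' @export
merge_small_clusters <- function(assignment, g, min_size = 10) {
  stopifnot(all(igraph::V(g)$name %in% names(assignment)))
  memb <- assignment
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0)
  repeat {
    sizes <- table(memb)
    small <- names(sizes)[sizes < min_size]
    if (!length(small)) break
    small <- small[order(sizes[small],
                         as.integer(small))]  # ascending size, then ID
    merged_any <- FALSE
    for (cl in small) {
      cross <- xor(memb[el[, 1]] == as.integer(cl),
                   memb[el[, 2]] == as.integer(cl))
      if (!any(cross)) next
      other <- ifelse(memb[el[cross, 1]] == as.integer(cl),
                      memb[el[cross, 2]], memb[el[cross, 1]])
      totals <- tapply(w[cross], other, sum)
      target <- as.integer(names(totals)[order(-totals,
                                               as.integer(names(totals)))][1])
      memb[memb == as.integer(cl)] <- target
      merged_any <- TRUE
      break  # re-evaluate sizes after each merge
    }
    if (!merged_any) break
  }
  relabel_by_size(memb)
}
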