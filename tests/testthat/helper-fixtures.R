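# Shared fixture builders and independent oracles. Everything here is
# deliberately written with plain base R, independent of the package's
# implementation paths, so it can serve as a cross-check.

make_sce <- function(counts, stage = "S1", mito = rep(FALSE, nrow(counts))) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  }
  if (length(stage) == 1) stage <- rep(stage, ncol(counts))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix")),
    rowData = S4Vectors::DataFrame(gene_id = rownames(counts),
                                   gene_name = rownames(counts),
                                   mito = mito, row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(barcode = colnames(counts), stage = stage,
                                   row.names = colnames(counts)))
}

# small synthetic spec for fast unit tests; baselines denser than the
# study-scale default so 300-gene cells clear the 700-UMI QC cutoff
tiny_spec <- function(seed = 1, ...) {
  synthetic_spec(
    n_genes = 300,
    cell_types = data.frame(type_id = c("A", "B"),
                            n_cells_stage1 = c(60, 0),
                            n_cells_stage2 = c(0, 60)),
    n_markers_per_type = 10, n_modules = 2, module_size = 15,
    mito_genes = 5, base_meanlog = log(2), base_sdlog = 1,
    marker_meanlog = log(2), seed = seed, ...)
}

# rename planted cell-type truth to merged (stage-suffixed) barcodes
truth_types_merged <- function(truth) {
  stats::setNames(truth$cell_type,
                  paste0(names(truth$cell_type), "-",
                         sub("_.*", "", names(truth$cell_type))))
}

# dense reference MCL, written independently of the package's sparse path
dense_mcl <- function(adj, inflation = 1.6, expansion = 2, max_iter = 200,
                      tol = 1e-6, prune = 1e-5) {
  n <- nrow(adj)
  loop <- apply(adj, 2, max)
  loop[loop == 0] <- 1
  m <- adj
  diag(m) <- loop
  m <- sweep(m, 2, colSums(m), "/")
  for (it in seq_len(max_iter)) {
    m2 <- m
    for (e in seq_len(expansion - 1)) m2 <- m2 %*% m
    m2 <- m2^inflation
    m2[m2 < prune] <- 0
    cs <- colSums(m2)
    for (j in which(cs == 0)) m2[which.max(m[, j]), j] <- 1
    m2 <- sweep(m2, 2, colSums(m2), "/")
    if (max(abs(m2 - m)) < tol) { m <- m2; break }
    m <- m2
  }
  # clusters: connected components of the support, via simple BFS
  supp <- (m > 0) | t(m > 0)
  memb <- rep(0L, n)
  cl <- 0L
  for (s in seq_len(n)) {
    if (memb[s] > 0) next
    cl <- cl + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (memb[v] > 0) next
      memb[v] <- cl
      queue <- c(queue, which(supp[v, ] & memb == 0))
    }
  }
  memb
}

# all set partitions of 1..n (Bell number growth; keep n small)
enum_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in enum_partitions(n - 1)) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# weighted modularity from first principles
modularity_by_hand <- function(g, membership, gamma = 1) {
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  a <- matrix(0, n, n)
  for (e in seq_len(nrow(el))) {
    a[el[e, 1], el[e, 2]] <- a[el[e, 1], el[e, 2]] + w[e]
    a[el[e, 2], el[e, 1]] <- a[el[e, 2], el[e, 1]] + w[e]
  }
  k <- rowSums(a)
  m2 <- sum(k)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + a[i, j] - gamma * k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

# a reduced synthetic layout that runs the full pipeline quickly but keeps
# comfortable margins at every stage (library sizes, type separation)
toy_pipeline_cfg <- function(...) {
  utils::modifyList(
    list(synthetic = list(
           n_genes = 600, base_meanlog = log(1), base_sdlog = 1,
           marker_meanlog = log(2),
           cell_types = list(type_id = c("A", "B", "C"),
                             n_cells_stage1 = c(80, 40, 0),
                             n_cells_stage2 = c(0, 40, 80)),
           n_markers_per_type = 25, n_modules = 2, module_size = 20),
         jackstraw = list(n_reps = 30),
         pca = list(n_pcs = 10)),
    list(...))
}
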