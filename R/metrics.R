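#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table via the
#' standard pair-counting formula; 1 means identical partitions, values
#' near 0 mean chance-level agreement.
#'
#' @param a,b Two label vectors over the same items (matched by name when
#'   both are named, by position otherwise).
#' @return The ARI as a numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Best-match Jaccard recovery of planted gene modules
#'
#' For every reference set (planted module), finds the recovered cluster
#' with the highest Jaccard index against it and returns those best-match
#' values.
#'
#' @param assignment Named vector gene -> recovered cluster ID.
#' @param reference Either a named list of gene-ID vectors, or a named
#'   vector gene -> module ID with `NA` for unplanted genes.
#' @return Named numeric vector of best-match Jaccard indices, one per
#'   reference set.
#' @export
best_match_jaccard <- function(assignment, reference) {
  if (!is.list(reference)) {
    reference <- split(names(reference)[!is.na(reference)],
                       reference[!is.na(reference)])
  }
  clusters <- split(names(assignment), assignment)
  vapply(reference, function(ref) {
    if (!length(clusters)) return(0)
    max(vapply(clusters, function(cl) {
      length(intersect(ref, cl)) / length(union(ref, cl))
    }, numeric(1)))
  }, numeric(1))
}

#' Per-cluster stage composition
#'
#' @param assignment Named integer vector cell -> cluster.
#' @param stage Named character vector cell -> stage label.
#' @return Data frame with one row per cluster: `cluster_id`, `n_cells`,
#'   one count column per stage, and `max_stage_frac`, the fraction of the
#'   dominant stage.
#' @export
cluster_stage_composition <- function(assignment, stage) {
  cells <- names(assignment)
  tab <- table(cluster = assignment[cells], stage = stage[cells])
  df <- data.frame(cluster_id = as.integer(rownames(tab)),
                   n_cells = as.integer(rowSums(tab)))
  for (st in colnames(tab)) df[[st]] <- as.integer(tab[, st])
  df$max_stage_frac <- apply(tab, 1, max) / rowSums(tab)
  df[order(df$cluster_id), ]
}
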