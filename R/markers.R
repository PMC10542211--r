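#' Wilcoxon rank-sum marker detection, one cluster versus the rest
#'
#' For every cluster (or cluster-stage group), genes are pre-filtered to
#' those detected in at least `min_pct` of cells on at least one side of
#' the contrast and with an absolute log2 fold change of at least
#' `logfc_min`, then tested with a two-sided Wilcoxon rank-sum test of the
#' cluster's cells against all remaining cells. The normal approximation
#' with tie correction and continuity correction is used, except when both
#' groups have at most 25 cells and the gene's values are tie-free, where
#' the exact null distribution is used. P-values are Bonferroni-adjusted
#' over the genes tested within each cluster.
#'
#' The fold change is computed on de-logged expression with a unit
#' pseudocount: `log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`.
#'
#' @param sce A `SingleCellExperiment` with a `logcounts` assay.
#' @param assignment Named integer vector cell -> cluster covering all
#'   cells.
#' @param min_pct Minimum detection fraction on the denser side.
#' @param logfc_min Minimum |log2 fold change|.
#' @param group_by_stage If `TRUE`, contrast (cluster, stage) groups
#'   instead of clusters.
#' @return A data frame of marker records: `gene`, `cluster`, `log2_fc`,
#'   `pct_in`, `pct_out`, `p_value`, `adj_p_value`, sorted by cluster then
#'   adjusted p.
#' @export
wilcoxon_markers <- function(sce, assignment, min_pct = 0.1,
                             logfc_min = 0.25, group_by_stage = FALSE) {
  cells <- colnames(sce)
  stopifnot(all(cells %in% names(assignment)))
  grp <- as.character(assignment[cells])
  if (group_by_stage) grp <- paste0(grp, ".", as.character(sce$stage))
  groups <- sort(unique(grp))
  if (length(groups) < 2) stop("at least two clusters are required")
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  expm <- expm1(x)
  detected <- x > 0
  ranks <- t(apply(x, 1, rank))        # per-gene ranks over all cells
  # per-gene tie term sum(t^3 - t) for the variance correction
  tie_term <- apply(x, 1, function(v) {
    t <- table(v)
    sum(t^3 - t)
  })
  n <- length(cells)
  out <- list()
  for (g in groups) {
    in_idx <- which(grp == g)
    out_idx <- which(grp != g)
    n1 <- length(in_idx); n2 <- length(out_idx)
    if (n1 < 2) {
      warning("cluster ", g, " has fewer than 2 cells; skipped")
      next
    }
    pct_in <- rowMeans(detected[, in_idx, drop = FALSE])
    pct_out <- rowMeans(detected[, out_idx, drop = FALSE])
    l2fc <- log2((rowMeans(expm[, in_idx, drop = FALSE]) + 1) /
                   (rowMeans(expm[, out_idx, drop = FALSE]) + 1))
    test <- which(pmax(pct_in, pct_out) >= min_pct & abs(l2fc) >= logfc_min)
    if (!length(test)) next
    w_stat <- rowSums(ranks[test, in_idx, drop = FALSE]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term[test] / (n * (n - 1)))
    z <- w_stat - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- pmin(1, 2 * stats::pnorm(-abs(z)))
    p[sigma2 == 0] <- 1
    if (n1 <= 25 && n2 <= 25) {
      for (i in seq_along(test)) {
        gi <- test[i]
        if (tie_term[gi] == 0) {
          u <- w_stat[i]
          p[i] <- if (u > mu) {
            min(1, 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
          } else {
            min(1, 2 * stats::pwilcox(u, n1, n2))
          }
        }
      }
    }
    out[[g]] <- data.frame(gene = rownames(x)[test], cluster = g,
                           log2_fc = l2fc[test], pct_in = pct_in[test],
                           pct_out = pct_out[test], p_value = p,
                           adj_p_value = pmin(1, p * length(test)),
                           row.names = NULL)
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), cluster = character(0),
                      log2_fc = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), p_value = numeric(0),
                      adj_p_value = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$cluster, res$adj_p_value, res$p_value, res$gene), ]
  rownames(res) <- NULL
  res
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the p-value is the upper-tail hypergeometric
#' probability of drawing at least the observed overlap when sampling
#' `length(query)` genes without replacement from the universe. Sets are
#' intersected with the universe first; adjustment is Benjamini-Hochberg
#' across sets.
#'
#' @param query Character vector of query genes (must be a subset of
#'   `universe`).
#' @param sets Named list of gene-ID vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of all considered genes.
#' @return Data frame `set_id`, `set_size`, `overlap`, `p`, `adj_p`,
#'   sorted by `adj_p` then `p`.
#' @export
ora_enrichment <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query contains genes outside the universe")
  }
  rows <- lapply(names(sets), function(id) {
    s <- intersect(unique(sets[[id]]), universe)
    if (!length(s)) return(NULL)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, length(s), length(universe) - length(s),
                       length(query), lower.tail = FALSE)
    data.frame(set_id = id, set_size = length(s), overlap = k, p = p)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(set_id = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      adj_p = numeric(0)))
  }
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$adj_p, res$p, res$set_id), ]
  rownames(res) <- NULL
  res
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_id <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of gene-ID character vectors; descriptions in
#'   attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' Map gene IDs through a homolog table
#'
#' Applies a two-column mapping (source gene -> target gene), dropping
#' genes without a mapping; used to translate genes into the namespace of
#' an external gene-set collection before over-representation analysis.
#'
#' @param genes Character vector of source gene IDs.
#' @param map Data frame whose first two columns are source and target
#'   IDs, or a path to a headerless two-column TSV.
#' @return Character vector of unique mapped target IDs.
#' @export
map_homologs <- function(genes, map) {
  if (is.character(map) && length(map) == 1) {
    map <- utils::read.table(map, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  }
  unique(map[[2]][match(genes, map[[1]], nomatch = 0)])
}
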