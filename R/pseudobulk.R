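#' Zero out unreliably measured genes within a cell cluster
#'
#' Given the log-normalized expression submatrix of one cell cluster, sets
#' a gene to zero in *all* cells of the cluster if any of three dropout /
#' low-signal conditions holds, all evaluated on the unfiltered submatrix:
#' (1) fewer than `min_cells` cells express the gene, (2) its maximum
#' expression across the cluster is below `min_max`, or (3) fewer than
#' `min_frac` of the cluster's cells express it. "Expressed" means a
#' strictly positive log-normalized value.
#'
#' @param m Dense or sparse genes x cells matrix of log-normalized values
#'   for one cluster.
#' @param min_cells Minimum number of expressing cells.
#' @param min_max Minimum of the per-gene maximum expression.
#' @param min_frac Minimum fraction of expressing cells.
#' @return The matrix with failing genes zeroed.
#' @export
apply_expression_filters <- function(m, min_cells = 3, min_max = 0.5,
                                     min_frac = 0.05) {
  if (ncol(m) < 1) stop("cluster must contain at least one cell")
  m <- as.matrix(m)
  n_expr <- rowSums(m > 0)
  max_expr <- apply(m, 1, max)
  frac_expr <- n_expr / ncol(m)
  zero <- n_expr < min_cells | max_expr < min_max | frac_expr < min_frac
  m[zero, ] <- 0
  m
}

#' Cap values at an upper percentile
#'
#' Replaces values above the `q`-th percentile with the percentile itself.
#' The percentile is computed over all supplied values (zeros included) by
#' linear interpolation between order statistics (R quantile type 7).
#'
#' @param values Numeric vector (one gene across the cells of a cluster).
#' @param q Percentile in (0, 100].
#' @return The capped vector.
#' @export
cap_at_percentile <- function(values, q = 95) {
  stopifnot(length(values) >= 1)
  cap <- stats::quantile(values, q / 100, type = 7, names = FALSE)
  values[values > cap] <- cap
  values
}

#' Aggregate cells into stage-differentiated cluster profiles
#'
#' For each cell cluster the expression filters
#' ([apply_expression_filters()]) and the per-gene percentile cap
#' ([cap_at_percentile()]) are applied over the whole cluster (both stages
#' pooled), then the arithmetic mean per gene is taken separately for each
#' developmental stage present in the cluster. A cluster containing cells
#' of both stages therefore contributes two columns; a single-stage
#' cluster one. Setting `per_stage_filters = TRUE` instead evaluates the
#' filters and cap within each (cluster, stage) group.
#'
#' @param sce A `SingleCellExperiment` with a `logcounts` assay and stage
#'   labels in `colData`.
#' @param assignment Named integer vector cell -> cluster ID; every cell
#'   of `sce` must be covered.
#' @param min_cells,min_max,min_frac Passed to
#'   [apply_expression_filters()].
#' @param percentile Passed to [cap_at_percentile()].
#' @param per_stage_filters Evaluate filters per (cluster, stage) instead
#'   of per cluster.
#' @return A list of class `pseudobulk_matrix` with `profiles` (genes x
#'   stage-cluster matrix of mean filtered expression) and `meta` (data
#'   frame with `cluster_id`, `stage`, `n_cells` per column).
#' @export
aggregate_by_cluster_stage <- function(sce, assignment, min_cells = 3,
                                       min_max = 0.5, min_frac = 0.05,
                                       percentile = 95,
                                       per_stage_filters = FALSE) {
  cells <- colnames(sce)
  if (!all(cells %in% names(assignment))) {
    stop("assignment does not cover all cells")
  }
  memb <- assignment[cells]
  stage <- stats::setNames(as.character(sce$stage), cells)
  ln <- SummarizedExperiment::assay(sce, "logcounts")
  cols <- list(); meta <- list()
  for (cl in sort(unique(memb))) {
    cl_cells <- cells[memb == cl]
    groups <- if (per_stage_filters) {
      split(cl_cells, stage[cl_cells])
    } else {
      list(all = cl_cells)
    }
    for (grp in groups) {
      sub <- apply_expression_filters(ln[, grp, drop = FALSE],
                                      min_cells = min_cells,
                                      min_max = min_max,
                                      min_frac = min_frac)
      caps <- apply(sub, 1, stats::quantile, probs = percentile / 100,
                    type = 7, names = FALSE)
      sub <- pmin(sub, matrix(caps, nrow(sub), ncol(sub)))
      for (st in sort(unique(stage[grp]))) {
        st_cells <- grp[stage[grp] == st]
        cols[[length(cols) + 1L]] <-
          rowMeans(sub[, st_cells, drop = FALSE])
        meta[[length(meta) + 1L]] <-
          data.frame(cluster_id = cl, stage = st,
                     n_cells = length(st_cells))
      }
    }
  }
  meta <- do.call(rbind, meta)
  profiles <- do.call(cbind, cols)
  colnames(profiles) <- paste0("C", meta$cluster_id, ".", meta$stage)
  rownames(profiles) <- rownames(sce)
  structure(list(profiles = profiles, meta = meta),
            class = "pseudobulk_matrix")
}

#' Write a pseudobulk matrix as TSV
#'
#' Columns are stage-differentiated clusters; three header comment lines
#' record cluster IDs, stages and cell counts.
#'
#' @param pb A `pseudobulk_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pseudobulk <- function(pb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#cluster_id\t", paste(pb$meta$cluster_id, collapse = "\t")),
               paste0("#stage\t", paste(pb$meta$stage, collapse = "\t")),
               paste0("#n_cells\t", paste(pb$meta$n_cells, collapse = "\t"))),
             con)
  df <- data.frame(gene_id = rownames(pb$profiles), pb$profiles,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
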