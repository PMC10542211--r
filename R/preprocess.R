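#' Filter cells on library size and mitochondrial content
#'
#' Removes cells whose total UMI count is `<= min_umi` or whose
#' mitochondrial UMI fraction is `>= max_mito` (both boundaries are
#' removed). Per-stage removal counts are attached as attribute
#' `"qc_report"` and emitted with `message()`.
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay and a logical
#'   `mito` column in `rowData`.
#' @param min_umi Cells with total UMI `<= min_umi` are removed.
#' @param max_mito Cells with mitochondrial fraction `>= max_mito` are
#'   removed.
#' @return The filtered `SingleCellExperiment`; `colData` gains
#'   `total_counts` and `mito_frac`.
#' @export
filter_cells <- function(sce, min_umi = 700, max_mito = 0.10) {
  cnt <- SummarizedExperiment::assay(sce, "counts")
  mito <- SummarizedExperiment::rowData(sce)$mito
  if (is.null(mito)) stop("rowData(sce)$mito is required")
  tot <- Matrix::colSums(cnt)
  mito_tot <- if (any(mito)) Matrix::colSums(cnt[mito, , drop = FALSE]) else
    rep(0, ncol(cnt))
  frac <- ifelse(tot > 0, mito_tot / tot, 1)
  low_umi <- tot <= min_umi
  high_mito <- frac >= max_mito
  keep <- !low_umi & !high_mito
  rep_df <- as.data.frame(table(stage = sce$stage,
                                removed_low_umi = low_umi,
                                removed_high_mito = high_mito))
  per_stage <- do.call(rbind, lapply(split(seq_len(ncol(sce)), sce$stage),
    function(i) data.frame(n_cells = length(i),
                           removed_low_umi = sum(low_umi[i]),
                           removed_high_mito = sum(high_mito[i]),
                           kept = sum(keep[i]))))
  message("filter_cells: removed ", sum(low_umi), " low-UMI and ",
          sum(high_mito), " high-mito cells (", sum(!keep),
          " total); kept ", sum(keep))
  if (!any(keep)) warning("no cells remain after QC filtering")
  out <- sce[, keep]
  out$total_counts <- tot[keep]
  out$mito_frac <- frac[keep]
  attr(out, "qc_report") <- per_stage
  out
}

#' Filter genes by detection across cells
#'
#' Keeps genes with a nonzero count in at least `min_cells` cells; the
#' default removes genes expressed in 3 or fewer cells.
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay.
#' @param min_cells Minimum number of cells with a nonzero count.
#' @return The filtered `SingleCellExperiment`.
#' @export
filter_genes <- function(sce, min_cells = 4) {
  cnt <- SummarizedExperiment::assay(sce, "counts")
  n_cells_expr <- Matrix::rowSums(cnt > 0)
  keep <- n_cells_expr >= min_cells
  message("filter_genes: removed ", sum(!keep), " of ", length(keep),
          " genes detected in fewer than ", min_cells, " cells")
  sce[keep, ]
}

#' Log-normalize UMI counts
#'
#' `value = ln(1 + count / cell_total * scale_factor)`, stored as the
#' `logcounts` assay. Zeros map to exactly zero and normalized values are
#' invariant to uniform scaling of a cell's counts.
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay.
#' @param scale_factor Library-size scaling constant.
#' @return `sce` with a sparse `logcounts` assay; `colData` gains
#'   `total_counts` and `mito_frac` if absent.
#' @export
log_normalize <- function(sce, scale_factor = 1e4) {
  cnt <- methods::as(SummarizedExperiment::assay(sce, "counts"),
                     "CsparseMatrix")
  tot <- Matrix::colSums(cnt)
  if (any(tot == 0)) {
    stop("cell(s) with zero total count: ",
         paste(utils::head(colnames(cnt)[tot == 0], 3), collapse = ", "))
  }
  ln <- cnt
  if (length(ln@x)) {
    percol <- rep.int(tot, diff(ln@p))
    ln@x <- log1p(ln@x / percol * scale_factor)
  }
  SummarizedExperiment::assay(sce, "logcounts") <- ln
  if (is.null(sce$total_counts)) sce$total_counts <- tot
  if (is.null(sce$mito_frac)) {
    mito <- SummarizedExperiment::rowData(sce)$mito
    mito_tot <- if (!is.null(mito) && any(mito))
      Matrix::colSums(cnt[mito, , drop = FALSE]) else rep(0, ncol(cnt))
    sce$mito_frac <- mito_tot / tot
  }
  sce
}

row_stats <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  v <- (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
  list(mean = mu, var = pmax(v, 0))
}

#' Select highly variable genes
#'
#' Two selection statistics are available. `"dispersion"` (default) is the
#' binned standardized dispersion: the log variance-to-mean ratio of the
#' log-normalized expression is z-scored within 20 equal-width bins of mean
#' log-expression, which removes the mean-dispersion trend so that genes
#' with excess variance relative to peers of similar abundance score high.
#' `"sd"` selects on the plain standard deviation of log-expression, for a
#' literal reading of an "sd > 0.5" rule. Both modes additionally require
#' the mean log-expression to lie strictly inside `(mean_low, mean_high)`.
#'
#' @param sce A `SingleCellExperiment` with a `logcounts` assay.
#' @param mean_low,mean_high Open interval of admissible mean
#'   log-expression.
#' @param disp_cutoff Cutoff on the selection statistic (z-scored
#'   dispersion or sd, depending on `method`).
#' @param method `"dispersion"` or `"sd"`.
#' @param n_bins Number of equal-width mean bins for `"dispersion"`.
#' @return Character vector of gene IDs sorted by decreasing statistic.
#' @export
find_variable_genes <- function(sce, mean_low = 0.0125, mean_high = 3,
                                disp_cutoff = 0.5,
                                method = c("dispersion", "sd"),
                                n_bins = 20) {
  method <- match.arg(method)
  if (ncol(sce) < 2) stop("at least two cells are required")
  ln <- SummarizedExperiment::assay(sce, "logcounts")
  st <- row_stats(ln)
  in_window <- st$mean > mean_low & st$mean < mean_high
  if (method == "sd") {
    stat <- sqrt(st$var)
  } else {
    expressed <- st$mean > 0
    d <- rep(NA_real_, nrow(ln))
    d[expressed] <- log(st$var[expressed] / st$mean[expressed])
    # constant genes: variance is zero up to float noise; drop from bins
    zero_var <- st$var <= 1e-12 * (st$mean^2 + 1)
    d[expressed & zero_var] <- -Inf
    brk <- seq(min(st$mean[expressed]), max(st$mean[expressed]),
               length.out = n_bins + 1)
    bin <- cut(st$mean, breaks = brk, include.lowest = TRUE)
    stat <- rep(NA_real_, nrow(ln))
    for (lv in levels(bin)) {
      i <- which(bin == lv & expressed & is.finite(d))
      if (!length(i)) next
      mu_b <- mean(d[i])
      sd_b <- stats::sd(d[i])
      stat[i] <- if (length(i) < 2 || !isTRUE(sd_b > 0)) 0 else
        (d[i] - mu_b) / sd_b
    }
  }
  keep <- which(in_window & !is.na(stat) & stat > disp_cutoff)
  if (!length(keep)) message("find_variable_genes: no genes selected")
  keep <- keep[order(-stat[keep], keep)]
  rownames(ln)[keep]
}

#' Regress out technical covariates and scale
#'
#' For each selected gene, fits ordinary least squares of log-expression on
#' an intercept plus the technical covariates (library size and
#' mitochondrial fraction by default), standardizes the residuals to unit
#' variance and clips them to `[-clip, clip]`. Zero-variance covariates are
#' dropped with a warning; zero-variance residual rows become all-zero.
#'
#' @param sce A `SingleCellExperiment` with `logcounts`, `total_counts` and
#'   `mito_frac`.
#' @param genes Gene IDs to scale (typically from
#'   [find_variable_genes()]).
#' @param covariates Character vector of `colData` column names to regress
#'   out.
#' @param clip Clipping bound on the scaled residuals.
#' @return A dense genes x cells matrix of scaled residuals.
#' @export
regress_and_scale <- function(sce, genes,
                              covariates = c("total_counts", "mito_frac"),
                              clip = 10) {
  stopifnot(all(genes %in% rownames(sce)))
  y <- t(as.matrix(SummarizedExperiment::assay(sce, "logcounts")[genes, ,
                                                                 drop = FALSE]))
  x <- cbind(intercept = rep(1, ncol(sce)))
  for (cv in covariates) {
    v <- sce[[cv]]
    if (is.null(v)) stop("covariate not found in colData: ", cv)
    if (stats::var(v) == 0) {
      warning("covariate '", cv, "' has zero variance; dropped")
    } else {
      x <- cbind(x, v)
      colnames(x)[ncol(x)] <- cv
    }
  }
  beta <- solve(crossprod(x), crossprod(x, y))
  res <- y - x %*% beta                     # cells x genes
  sds <- apply(res, 2, stats::sd)
  # residuals that are zero up to numerical noise become all-zero rows
  degenerate <- sds <= 1e-8 * pmax(apply(y, 2, stats::sd), 1)
  res[, degenerate] <- 0
  sds[degenerate] <- 1
  res <- sweep(res, 2, sds, "/")
  res[res > clip] <- clip
  res[res < -clip] <- -clip
  out <- t(res)
  dimnames(out) <- list(genes, colnames(sce))
  out
}

# Right singular vectors and singular values of a cells x genes matrix via
# the spectral decomposition of the gene-gene crossproduct (faster than a
# full SVD when loadings are the target, as in the JackStraw replicates).
pca_eigen <- function(x, n_pcs) {
  eig <- eigen(crossprod(x), symmetric = TRUE)
  list(d = sqrt(pmax(eig$values[seq_len(n_pcs)], 0)),
       v = eig$vectors[, seq_len(n_pcs), drop = FALSE])
}

#' Principal component analysis of the scaled matrix
#'
#' Singular value decomposition of the cells x genes scaled matrix. Scores
#' are cell coordinates `U %*% diag(d)`; the sign of each component is
#' fixed so its largest-magnitude gene loading is positive, making output
#' independent of SVD sign conventions.
#'
#' @param sm Scaled genes x cells matrix from [regress_and_scale()].
#' @param n_pcs Number of components; must be at most
#'   `min(n_genes, n_cells) - 1`.
#' @return A list of class `pc_space` with `scores` (cells x n_pcs),
#'   `loadings` (genes x n_pcs), `sdev`, `var_explained`, and placeholders
#'   `p_values` / `selected_pcs` filled by [jackstraw()].
#' @export
run_pca <- function(sm, n_pcs = 20) {
  if (n_pcs > min(nrow(sm), ncol(sm) - 1)) {
    stop("n_pcs (", n_pcs, ") exceeds min(n_genes, n_cells - 1) = ",
         min(nrow(sm), ncol(sm) - 1))
  }
  x <- t(sm)
  eig <- pca_eigen(x, n_pcs)
  d <- eig$d
  loadings <- eig$v
  scores <- x %*% loadings
  flip <- apply(loadings, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  loadings <- sweep(loadings, 2, flip, "*")
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(n_pcs)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(n_pcs)))
  total_var <- sum(x^2)
  structure(list(scores = scores, loadings = loadings,
                 sdev = d / sqrt(nrow(x) - 1),
                 var_explained = d^2 / total_var,
                 p_values = rep(NA_real_, n_pcs),
                 selected_pcs = integer(0)),
            class = "pc_space")
}

#' JackStraw significance test for principal components
#'
#' In each replicate a random fraction `prop` of gene rows is permuted
#' across cells and the PCA loadings are recomputed; the permuted genes'
#' absolute loadings are pooled into a null distribution per component.
#' Each observed gene loading gets an empirical p-value against that null
#' (the fraction of null loadings at least as large, which is zero for a
#' loading exceeding the whole null). The per-component p-value is a
#' one-sided two-sample proportion test of the fraction of genes with
#' empirical p below `score_thresh` against `score_thresh` itself, and
#' components with `p < alpha` are selected.
#'
#' Before comparison the null of each component is rescaled so its median
#' matches the observed median: genes present in the analyzed matrix helped
#' define the fitted components (they are eigenvectors of this realization),
#' so for low-variance components the freshly permuted genes' loadings are
#' systematically smaller than those of ordinary undifferentiated genes;
#' median matching calibrates the bulk of the null while leaving a genuine
#' signal tail detectable.
#'
#' @param sm Scaled genes x cells matrix.
#' @param pcs A `pc_space` from [run_pca()].
#' @param n_reps Number of permutation replicates (>= 20).
#' @param prop Fraction of genes permuted per replicate; `prop * n_genes`
#'   must be at least 1.
#' @param alpha Per-component significance level.
#' @param score_thresh Empirical-p threshold defining a "significant" gene
#'   loading in the proportion-test aggregation.
#' @param seed Optional integer seed for the permutations.
#' @return `pcs` with `p_values` and `selected_pcs` filled in.
#' @export
jackstraw <- function(sm, pcs, n_reps = 100, prop = 0.01, alpha = 0.05,
                      score_thresh = 1e-5, seed = NULL) {
  stopifnot(n_reps >= 20)
  n_genes <- nrow(sm)
  n_perm <- floor(prop * n_genes)
  if (n_perm < 1) stop("prop * n_genes < 1: no genes to permute")
  n_pcs <- ncol(pcs$scores)
  run <- function() {
    null_load <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      idx <- sample.int(n_genes, n_perm)
      smp <- sm
      for (i in idx) smp[i, ] <- smp[i, sample.int(ncol(sm))]
      v <- pca_eigen(t(smp), n_pcs)$v
      null_load[[r]] <- abs(v[idx, , drop = FALSE])
    }
    do.call(rbind, null_load)
  }
  null_mat <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  obs <- abs(pcs$loadings)
  p_pc <- numeric(n_pcs)
  for (j in seq_len(n_pcs)) {
    med_null <- stats::median(null_mat[, j])
    med_obs <- stats::median(obs[, j])
    scl <- if (med_null > 0 && med_obs > 0) med_obs / med_null else 1
    null_j <- sort(null_mat[, j] * scl)
    # empirical p: fraction of null loadings >= observed (0 if none)
    ge <- length(null_j) - findInterval(obs[, j], null_j,
                                        left.open = TRUE)
    emp_p <- ge / length(null_j)
    x <- sum(emp_p < score_thresh)
    p_pc[j] <- if (x == 0) 1 else suppressWarnings(
      stats::prop.test(c(x, round(score_thresh * n_genes)),
                       c(n_genes, n_genes),
                       alternative = "greater")$p.value)
  }
  pcs$p_values <- p_pc
  pcs$selected_pcs <- which(p_pc < alpha)
  pcs
}
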