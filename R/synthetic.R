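#' Specification for a synthetic two-stage UMI dataset
#'
#' Builds the parameter object consumed by [generate_dataset()]. The
#' generative model is a gamma-Poisson (negative binomial): for gene g and
#' cell c the expected count is
#' `mu_gc = s_c * b_g * marker_fold^[g marker of type(c)] * a_mc^[g in module m]`
#' where `s_c` is a log-normal cell size factor, `b_g` a log-normal gene
#' baseline, and `a_mc` a log-normal module activity with a cell-type level
#' component (so module genes covary across cells *and* across cell
#' clusters). Counts are `NB(mu_gc, size = 1/dispersion)`. Dropout zeros
#' arise naturally from low means; no explicit zero-inflation term is used.
#'
#' The default emulates, at desk scale, a two-stage whole-organism pupal
#' dataset: 10 planted cell types of which 3 occur only at stage 1, 5 only
#' at stage 2 and 2 at both stages; roughly 400 cells per stage and 2,000
#' genes; 20 marker genes per type; 4 planted coexpression modules of 30
#' genes; 13 mitochondrial genes contributing ~5% of UMIs per cell.
#'
#' @param n_genes Total number of genes (mitochondrial genes included).
#' @param cell_types Data frame with columns `type_id`, `n_cells_stage1`,
#'   `n_cells_stage2`. A type with zero cells at one stage is
#'   stage-specific.
#' @param n_markers_per_type Number of marker genes planted per cell type;
#'   marker sets are disjoint across types.
#' @param marker_fold Multiplicative mean shift of a marker gene in its own
#'   type (> 1).
#' @param base_meanlog,base_sdlog Log-normal parameters of the per-gene
#'   baseline mean `b_g`.
#' @param marker_meanlog,marker_sdlog Log-normal parameters used to re-draw
#'   baselines of marker genes, so planted markers sit on moderately
#'   expressed genes rather than on near-zero ones.
#' @param module_meanlog,module_sdlog Log-normal parameters used to re-draw
#'   baselines of planted module genes. The default puts module genes at
#'   high expression, where the averaged pseudobulk profile has little
#'   sampling noise relative to the module activity signal -- coexpression
#'   detection over a modest number of stage-cluster columns is only
#'   well-posed for such genes.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi mu^2`); `size = 1/phi`.
#' @param libsize_sigma Log-normal sigma of the per-cell size factor.
#' @param mito_genes Number of mitochondrial genes.
#' @param mito_mean_frac Expected fraction of a cell's UMIs that are
#'   mitochondrial.
#' @param n_modules Number of planted coexpressed gene modules (disjoint
#'   from each other and from marker genes).
#' @param module_size Genes per module.
#' @param module_type_sd,module_cell_sd Standard deviations (log scale) of
#'   the cell-type level and cell level components of module activity.
#' @param type_het_sd Standard deviation (log scale) of optional
#'   per-(gene, type) expression heterogeneity for background genes. The
#'   default of 0 makes background genes carry no systematic cell-type
#'   structure, so the planted modules are the only true coexpression in
#'   the data and the ground-truth contract (`module_of = NA` means "not
#'   coexpressed") is exact. Setting it above 0 emulates the broad
#'   type-dependence of real transcriptomes, at the cost of background
#'   genes forming genuine (unplanted) coexpression with chance partners.
#'   Never applied to module genes (their type-dependence is carried
#'   entirely by the shared module activity) or mitochondrial genes.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000,
                           cell_types = default_cell_types(),
                           n_markers_per_type = 20,
                           marker_fold = 8,
                           base_meanlog = log(0.05),
                           base_sdlog = 2.2,
                           marker_meanlog = 0,
                           marker_sdlog = 0.5,
                           module_meanlog = log(3),
                           module_sdlog = 0.4,
                           dispersion = 0.3,
                           libsize_sigma = 0.35,
                           mito_genes = 13,
                           mito_mean_frac = 0.05,
                           n_modules = 4,
                           module_size = 30,
                           module_type_sd = 0.8,
                           module_cell_sd = 0.3,
                           type_het_sd = 0,
                           seed = 1L) {
  stopifnot(is.data.frame(cell_types),
            all(c("type_id", "n_cells_stage1", "n_cells_stage2") %in%
                  names(cell_types)),
            marker_fold > 1, dispersion > 0, libsize_sigma >= 0,
            mito_mean_frac >= 0, mito_mean_frac < 1)
  if (nrow(cell_types) == 0) stop("at least one cell type is required")
  if (anyDuplicated(cell_types$type_id)) stop("duplicate type_id")
  needed <- nrow(cell_types) * n_markers_per_type +
    n_modules * module_size + mito_genes
  if (needed > n_genes) {
    stop("marker + module + mitochondrial genes (", needed,
         ") exceed n_genes (", n_genes, ")")
  }
  spec <- list(n_genes = n_genes, cell_types = cell_types,
               n_markers_per_type = n_markers_per_type,
               marker_fold = marker_fold,
               base_meanlog = base_meanlog, base_sdlog = base_sdlog,
               marker_meanlog = marker_meanlog, marker_sdlog = marker_sdlog,
               module_meanlog = module_meanlog, module_sdlog = module_sdlog,
               dispersion = dispersion, libsize_sigma = libsize_sigma,
               mito_genes = mito_genes, mito_mean_frac = mito_mean_frac,
               n_modules = n_modules, module_size = module_size,
               module_type_sd = module_type_sd,
               module_cell_sd = module_cell_sd,
               type_het_sd = type_het_sd,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

#' Default planted cell-type layout
#'
#' Ten types: 3 specific to stage 1, 5 specific to stage 2 and 2 shared,
#' giving ~400 cells per stage. Stage 2 carries more distinct types,
#' mirroring the expanding cellular diversity of late metamorphosis.
#'
#' @return A data frame with columns `type_id`, `n_cells_stage1`,
#'   `n_cells_stage2`.
#' @export
default_cell_types <- function() {
  data.frame(
    type_id = paste0("T", 1:10),
    n_cells_stage1 = c(100, 100, 100, 0, 0, 0, 0, 0, 50, 50),
    n_cells_stage2 = c(0, 0, 0, 60, 60, 60, 60, 60, 50, 50),
    stringsAsFactors = FALSE)
}

# Insect-style mitochondrial gene names (13 protein-coding mt genes).
mito_gene_names <- function(n) {
  base <- c("mt-ND1", "mt-ND2", "mt-ND3", "mt-ND4", "mt-ND4L", "mt-ND5",
            "mt-ND6", "mt-COX1", "mt-COX2", "mt-COX3", "mt-ATP6",
            "mt-ATP8", "mt-CYTB")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("mt-RNR", seq_len(n - length(base))))
}

#' Generate a synthetic two-stage dataset with ground truth
#'
#' Draws one UMI count matrix per developmental stage under the model
#' described in [synthetic_spec()], together with the ground truth needed
#' for recovery testing: the planted type of every cell, the planted module
#' (if any) of every gene, and the marker set of every type.
#'
#' @param spec A `synthetic_spec` object.
#' @return A list with elements:
#'   \describe{
#'     \item{stages}{named list of per-stage `SingleCellExperiment`s
#'       (stage labels `"S1"`, `"S2"`); stages with zero cells are
#'       included as 0-column objects.}
#'     \item{truth}{list with `cell_type` (named character vector over all
#'       barcodes), `module_of` (named vector over genes, `NA` for
#'       unplanted genes), `marker_genes` (list type_id -> gene IDs),
#'       `base_mean` (named numeric vector of `b_g`), and `qc_outlier`
#'       (empty here; filled by [generate_qc_outliers()]).}
#'   }
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  ct <- spec$cell_types
  n_types <- nrow(ct)
  gene_id <- sprintf("Gene%04d", seq_len(spec$n_genes))
  gene_name <- gene_id
  mito_idx <- integer(0)
  if (spec$mito_genes > 0) {
    mito_idx <- seq(spec$n_genes - spec$mito_genes + 1, spec$n_genes)
    gene_name[mito_idx] <- mito_gene_names(spec$mito_genes)
    gene_id[mito_idx] <- gene_name[mito_idx]
  }

  # gene baselines; markers and module genes re-drawn at moderate expression
  b <- stats::rlnorm(spec$n_genes, spec$base_meanlog, spec$base_sdlog)
  n_marker_genes <- n_types * spec$n_markers_per_type
  n_module_genes <- spec$n_modules * spec$module_size
  marker_gene_idx <- seq_len(n_marker_genes)
  module_gene_idx <- n_marker_genes + seq_len(n_module_genes)
  if (length(marker_gene_idx)) {
    b[marker_gene_idx] <- stats::rlnorm(length(marker_gene_idx),
                                        spec$marker_meanlog,
                                        spec$marker_sdlog)
  }
  if (length(module_gene_idx)) {
    b[module_gene_idx] <- stats::rlnorm(length(module_gene_idx),
                                        spec$module_meanlog,
                                        spec$module_sdlog)
  }
  # mitochondrial baselines scaled to hit the expected mito UMI fraction
  if (length(mito_idx)) {
    s_rest <- sum(b[-mito_idx])
    b[mito_idx] <- spec$mito_mean_frac / (1 - spec$mito_mean_frac) *
      s_rest / length(mito_idx)
  }

  marker_genes <- split(gene_id[marker_gene_idx],
                        rep(ct$type_id, each = spec$n_markers_per_type))
  marker_genes <- marker_genes[ct$type_id]
  module_of <- rep(NA_character_, spec$n_genes)
  if (n_module_genes) {
    module_of[module_gene_idx] <- rep(paste0("M", seq_len(spec$n_modules)),
                                      each = spec$module_size)
  }
  names(module_of) <- gene_id

  # per-(module, type) activity component shared by all cells of a type
  mod_type <- matrix(stats::rnorm(spec$n_modules * n_types, 0,
                                  spec$module_type_sd),
                     nrow = spec$n_modules, ncol = n_types,
                     dimnames = list(NULL, ct$type_id))

  # per-(gene, type) heterogeneity; module and mitochondrial genes exempt
  het <- matrix(0, nrow = spec$n_genes, ncol = n_types,
                dimnames = list(NULL, ct$type_id))
  if (spec$type_het_sd > 0) {
    het_genes <- setdiff(seq_len(spec$n_genes), c(module_gene_idx, mito_idx))
    het[het_genes, ] <- stats::rnorm(length(het_genes) * n_types, 0,
                                     spec$type_het_sd)
  }

  make_stage <- function(stage, n_per_type) {
    n_cells <- sum(n_per_type)
    if (n_cells == 0) {
      m <- Matrix::Matrix(0, nrow = spec$n_genes, ncol = 0, sparse = TRUE,
                          dimnames = list(gene_id, character(0)))
      return(SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(m, "CsparseMatrix")),
        rowData = S4Vectors::DataFrame(gene_id = gene_id,
                                       gene_name = gene_name,
                                       mito = seq_len(spec$n_genes) %in% mito_idx,
                                       row.names = gene_id)))
    }
    type_of <- rep(ct$type_id, n_per_type)
    barcode <- sprintf("%s_C%04d", stage, seq_len(n_cells))
    s <- stats::rlnorm(n_cells, 0, spec$libsize_sigma)
    mu <- b %o% s                                   # genes x cells baseline
    for (t in seq_len(n_types)) {
      cells_t <- which(type_of == ct$type_id[t])
      if (!length(cells_t)) next
      g_t <- marker_gene_idx[rep(ct$type_id, each = spec$n_markers_per_type)
                             [marker_gene_idx] == ct$type_id[t]]
      mu[g_t, cells_t] <- mu[g_t, cells_t] * spec$marker_fold
      mu[, cells_t] <- mu[, cells_t] * exp(het[, t])
    }
    if (spec$n_modules > 0) {
      for (mmod in seq_len(spec$n_modules)) {
        g_m <- module_gene_idx[(mmod - 1) * spec$module_size +
                                 seq_len(spec$module_size)]
        act <- exp(mod_type[mmod, type_of] +
                     stats::rnorm(n_cells, 0, spec$module_cell_sd))
        mu[g_m, ] <- mu[g_m, ] * rep(act, each = length(g_m))
      }
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / spec$dispersion),
                     nrow = spec$n_genes, ncol = n_cells,
                     dimnames = list(gene_id, barcode))
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(counts, "CsparseMatrix")),
      rowData = S4Vectors::DataFrame(gene_id = gene_id,
                                     gene_name = gene_name,
                                     mito = seq_len(spec$n_genes) %in% mito_idx,
                                     row.names = gene_id),
      colData = S4Vectors::DataFrame(barcode = barcode,
                                     stage = rep(stage, n_cells),
                                     type = type_of,
                                     row.names = barcode))
  }

  s1 <- make_stage("S1", ct$n_cells_stage1)
  s2 <- make_stage("S2", ct$n_cells_stage2)
  cell_type <- c(stats::setNames(as.character(s1$type), colnames(s1)),
                 stats::setNames(as.character(s2$type), colnames(s2)))
  names(b) <- gene_id
  list(stages = list(S1 = s1, S2 = s2),
       truth = list(cell_type = cell_type,
                    module_of = module_of,
                    marker_genes = marker_genes,
                    base_mean = b,
                    qc_outlier = character(0)))
}

#' Append engineered QC-violating cells
#'
#' Adds to stage 1 of a generated dataset cells that each violate exactly
#' one quality-control rule: `n_low_umi` cells with total UMI <= 700 (and
#' zero mitochondrial content, so only the UMI rule fires) and
#' `n_high_mito` cells with a mitochondrial fraction >= 0.10 but an ample
#' library (so only the mitochondrial rule fires). Outlier barcodes are
#' recorded in `truth$qc_outlier` with values `"low_umi"` / `"high_mito"`.
#'
#' @param dataset Output of [generate_dataset()].
#' @param spec The `synthetic_spec` that produced it.
#' @param n_low_umi Number of low-library cells to add.
#' @param n_high_mito Number of high-mitochondrial cells to add.
#' @return The modified dataset list.
#' @export
generate_qc_outliers <- function(dataset, spec, n_low_umi = 0,
                                 n_high_mito = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_low_umi == 0 && n_high_mito == 0) return(dataset)
  withr::with_seed(spec$seed + 104729L, {
    s1 <- dataset$stages$S1
    gene_id <- rownames(s1)
    mito <- SummarizedExperiment::rowData(s1)$mito
    n_new <- n_low_umi + n_high_mito
    b <- dataset$truth$base_mean
    prob_non_mito <- ifelse(mito, 0, b)
    cols <- matrix(0L, nrow = length(gene_id), ncol = n_new)
    kind <- c(rep("low_umi", n_low_umi), rep("high_mito", n_high_mito))
    for (j in seq_len(n_new)) {
      if (kind[j] == "low_umi") {
        tot <- sample(100:700, 1)
        cols[, j] <- stats::rmultinom(1, tot, prob_non_mito)
      } else {
        tot <- 2000 + sample(0:2000, 1)
        mito_tot <- ceiling(tot * stats::runif(1, 0.12, 0.30))
        prob_mito <- ifelse(mito, 1, 0)
        cols[, j] <- stats::rmultinom(1, tot - mito_tot, prob_non_mito) +
          stats::rmultinom(1, mito_tot, prob_mito)
      }
    }
    barcode <- sprintf("S1_QC%03d", seq_len(n_new))
    colnames(cols) <- barcode
    rownames(cols) <- gene_id
    new_counts <- cbind(SummarizedExperiment::assay(s1, "counts"),
                        methods::as(cols, "CsparseMatrix"))
    cd <- S4Vectors::DataFrame(
      barcode = c(colnames(s1), barcode),
      stage = rep("S1", ncol(new_counts)),
      type = c(as.character(s1$type), rep(NA_character_, n_new)),
      row.names = c(colnames(s1), barcode))
    dataset$stages$S1 <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = new_counts),
      rowData = SummarizedExperiment::rowData(s1),
      colData = cd)
    dataset$truth$qc_outlier <- stats::setNames(kind, barcode)
    dataset
  })
}
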