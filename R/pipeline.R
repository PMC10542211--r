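#' Default pipeline configuration
#'
#' Returns the full configuration tree with every tunable parameter at its
#' default. Defaults follow the whole-organism pupal analysis protocol this
#' package implements:
#' cells with <= 700 UMIs or >= 10% mitochondrial UMIs are removed, genes
#' detected in <= 3 cells are removed, variable genes require mean
#' log-expression in (0.0125, 3) and dispersion > 0.5, the cell graph uses
#' 20 nearest neighbours at r >= 0.77 with degree-< 3 pruning, MCL runs at
#' inflation 1.6, clusters under 10 cells are merged, pseudobulk zeroing
#' uses the 3-cell / 0.5 / 5% rules with a 95th-percentile cap, and the
#' gene network uses max expression > 0.2, 4 nearest neighbours at
#' r >= 0.7 and Louvain at resolution 0.65.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    input = list(bundles = NULL, mito_pattern = NULL, mito_ids = NULL),
    synthetic = list(enabled = TRUE, n_genes = 2000, cell_types = NULL,
                     n_markers_per_type = 20, marker_fold = 8,
                     base_meanlog = NULL, base_sdlog = NULL,
                     marker_meanlog = NULL, marker_sdlog = NULL,
                     module_meanlog = NULL, module_sdlog = NULL,
                     module_type_sd = NULL, module_cell_sd = NULL,
                     type_het_sd = NULL,
                     dispersion = 0.3, libsize_sigma = 0.35,
                     mito_genes = 13, mito_mean_frac = 0.05,
                     n_modules = 4, module_size = 30, seed = NULL),
    qc = list(min_umi = 700, max_mito = 0.10, min_cells_per_gene = 4),
    normalize = list(scale_factor = 10000),
    hvg = list(mean_low = 0.0125, mean_high = 3, disp_cutoff = 0.5,
               method = "dispersion", n_bins = 20),
    scale = list(clip = 10),
    pca = list(n_pcs = 20),
    jackstraw = list(n_reps = 100, prop = 0.01, alpha = 0.05,
                     score_thresh = 1e-5),
    cellnet = list(k = 20, r_min = 0.77, min_degree = 3),
    mcl = list(inflation = 1.6, expansion = 2, max_iter = 200,
               tol = 1e-6, prune = 1e-5),
    merge = list(min_size = 10),
    pseudobulk = list(min_cells = 3, min_max = 0.5, min_frac = 0.05,
                      percentile = 95, per_stage_filters = FALSE),
    gcn = list(min_max = 0.2, k = 4, r_min = 0.7, resolution = 0.65),
    markers = list(enabled = TRUE, min_pct = 0.1, logfc_min = 0.25,
                   group_by_stage = FALSE),
    enrich = list(gmt = NULL, homolog_map = NULL),
    seed = 1L)
}

merge_config <- function(user, template) {
  for (key in names(user)) {
    if (!key %in% names(template)) {
      stop("unknown configuration key: '", key, "'")
    }
    if (is.list(template[[key]]) && !is.null(names(template[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("configuration key '", key, "' must be a section")
      }
      template[[key]] <- merge_config(user[[key]], template[[key]])
    } else {
      template[[key]] <- user[[key]]
    }
  }
  template
}

#' Load and validate a pipeline configuration
#'
#' Merges a user configuration (a YAML file path or a nested list) over
#' [default_config()]. Unknown keys anywhere in the tree are rejected;
#' threshold ranges are sanity-checked.
#'
#' @param config A YAML file path, a nested list, or `NULL` for pure
#'   defaults.
#' @return The resolved configuration list.
#' @export
load_config <- function(config = NULL) {
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(config, default_config())
  stopifnot(cfg$qc$min_umi >= 0, cfg$qc$max_mito > 0, cfg$qc$max_mito <= 1,
            cfg$qc$min_cells_per_gene >= 0,
            cfg$cellnet$k >= 1, cfg$cellnet$r_min >= -1, cfg$cellnet$r_min <= 1,
            cfg$mcl$inflation > 1, cfg$gcn$k >= 1,
            cfg$gcn$resolution > 0, cfg$merge$min_size >= 0,
            cfg$jackstraw$alpha >= 0, cfg$jackstraw$alpha <= 1)
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes QC, normalization, variable-gene selection, scaling, PCA,
#' JackStraw, cell-graph construction, MCL clustering, small-cluster
#' merging, pseudobulk aggregation, gene-network inference, Louvain gene
#' clustering, marker detection and (if gene sets are configured)
#' over-representation analysis, writing every intermediate artifact, a
#' machine-readable manifest of per-stage counts and a log into `outdir`.
#' Identical configuration and seed produce byte-identical manifests.
#'
#' The one global seed is fanned out into independent child seeds for the
#' synthetic generator, JackStraw and Louvain, so each stochastic stage is
#' reproducible in isolation.
#'
#' @param config A YAML path, nested list, or `NULL` (see
#'   [load_config()]).
#' @param outdir Output directory, created if needed.
#' @param seed Optional integer overriding `config$seed`.
#' @return Invisibly, a list with the main in-memory results (`sce`,
#'   `pca`, `cell_graph`, `clusters`, `pseudobulk`, `gene_graph`,
#'   `gene_clusters`, `markers`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config = NULL, outdir, seed = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "log.txt")
  cat("", file = log_path)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(line, "\n", file = log_path, sep = "", append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  child_seeds <- withr::with_seed(cfg$seed, sample.int(2^31 - 1L, 4L))
  yaml::write_yaml(cfg, file.path(outdir, "resolved_config.yaml"))
  manifest <- list(seed = cfg$seed)

  # ---- input ----
  input <- stage("input", {
    if (!is.null(cfg$input$bundles)) {
      list(stages = lapply(cfg$input$bundles, function(b) {
        read_count_bundle(b$matrix, b$features, b$barcodes, b$stage,
                          mito_pattern = cfg$input$mito_pattern,
                          mito_ids = cfg$input$mito_ids)
      }), truth = NULL)
    } else if (isTRUE(cfg$synthetic$enabled)) {
      sp <- cfg$synthetic
      sp$enabled <- NULL
      if (is.null(sp$seed)) sp$seed <- child_seeds[1]
      if (is.null(sp$cell_types)) sp$cell_types <- NULL
      else sp$cell_types <- as.data.frame(lapply(sp$cell_types, unlist),
                                          stringsAsFactors = FALSE)
      sp <- sp[!vapply(sp, is.null, logical(1))]
      spec <- do.call(synthetic_spec, sp)
      generate_dataset(spec)
    } else {
      stop("no input bundles configured and synthetic generation disabled")
    }
  })
  stages_list <- input$stages
  truth <- input$truth
  if (!is.null(truth)) {
    utils::write.table(
      data.frame(barcode = paste0(names(truth$cell_type), "-",
                                  sub("_.*", "", names(truth$cell_type))),
                 type = unname(truth$cell_type)),
      file.path(outdir, "ground_truth_cell_types.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  merged <- stage("merge", merge_stages(stages_list))
  manifest$input <- list(
    n_stages = length(stages_list),
    cells_per_stage = as.list(table(merged$stage)),
    n_genes = nrow(merged))

  # ---- QC ----
  filtered <- stage("qc", filter_cells(merged, min_umi = cfg$qc$min_umi,
                                       max_mito = cfg$qc$max_mito))
  qc_rep <- attr(filtered, "qc_report")
  manifest$qc_cells <- lapply(seq_len(nrow(qc_rep)), function(i) {
    r <- qc_rep[i, ]
    list(stage = rownames(qc_rep)[i], n_cells = r$n_cells,
         removed_low_umi = r$removed_low_umi,
         removed_high_mito = r$removed_high_mito,
         removed_total = r$n_cells - r$kept, kept = r$kept)
  })
  if (ncol(filtered) == 0) {
    stop("pipeline stage 'qc' failed: no cells remain after quality control",
         call. = FALSE)
  }
  genes_before <- nrow(filtered)
  filtered <- stage("gene_filter",
                    filter_genes(filtered,
                                 min_cells = cfg$qc$min_cells_per_gene))
  manifest$qc_genes <- list(n_genes = genes_before,
                            removed = genes_before - nrow(filtered),
                            kept = nrow(filtered))
  logmsg("QC: ", ncol(filtered), " cells, ", nrow(filtered), " genes kept")

  # ---- normalize / HVG / scale / PCA / JackStraw ----
  nm <- stage("normalize",
              log_normalize(filtered,
                            scale_factor = cfg$normalize$scale_factor))
  hvg <- stage("hvg", find_variable_genes(
    nm, mean_low = cfg$hvg$mean_low, mean_high = cfg$hvg$mean_high,
    disp_cutoff = cfg$hvg$disp_cutoff, method = cfg$hvg$method,
    n_bins = cfg$hvg$n_bins))
  if (length(hvg) < 2) {
    stop("pipeline stage 'hvg' failed: fewer than 2 variable genes",
         call. = FALSE)
  }
  manifest$hvg <- list(n_variable_genes = length(hvg))
  sm <- stage("scale", regress_and_scale(nm, hvg, clip = cfg$scale$clip))
  n_pcs <- min(cfg$pca$n_pcs, min(dim(sm)) - 1)
  pca <- stage("pca", run_pca(sm, n_pcs = n_pcs))
  # guarantee at least one permuted gene per replicate on small gene sets
  prop_eff <- max(cfg$jackstraw$prop, 1.000001 / length(hvg))
  pca <- stage("jackstraw", jackstraw(
    sm, pca, n_reps = cfg$jackstraw$n_reps, prop = prop_eff,
    alpha = cfg$jackstraw$alpha, score_thresh = cfg$jackstraw$score_thresh,
    seed = child_seeds[2]))
  sel <- pca$selected_pcs
  if (length(sel) < 2) {
    warning("fewer than 2 significant PCs; using the first 2 PCs")
    sel <- 1:2
  }
  manifest$pca <- list(n_pcs_computed = n_pcs,
                       n_pcs_selected = length(sel),
                       selected_pcs = as.list(sel))
  logmsg("PCA: ", length(hvg), " variable genes, ", length(sel),
         " significant PCs")

  # ---- cell graph / MCL / merge ----
  cell_graph <- stage("cell_graph", {
    sim <- pairwise_pearson(pca$scores[, sel, drop = FALSE])
    build_knn_graph(sim, k = cfg$cellnet$k, r_min = cfg$cellnet$r_min)
  })
  manifest$cell_graph <- list(nodes = igraph::vcount(cell_graph),
                              edges = igraph::ecount(cell_graph))
  cell_graph <- stage("prune",
                      prune_low_degree(cell_graph,
                                       min_degree = cfg$cellnet$min_degree))
  manifest$pruned_graph <- list(nodes = igraph::vcount(cell_graph),
                                edges = igraph::ecount(cell_graph),
                                removed = manifest$cell_graph$nodes -
                                  igraph::vcount(cell_graph))
  if (igraph::vcount(cell_graph) == 0) {
    stop("pipeline stage 'cell_graph' failed: no cells remain in the graph",
         call. = FALSE)
  }
  write_graph_file(cell_graph, file.path(outdir, "cell_graph.tsv"),
                   "edgelist")
  clusters_raw <- stage("mcl", mcl_cluster(
    cell_graph, inflation = cfg$mcl$inflation,
    expansion = cfg$mcl$expansion, max_iter = cfg$mcl$max_iter,
    tol = cfg$mcl$tol, prune = cfg$mcl$prune))
  clusters <- stage("merge_clusters",
                    merge_small_clusters(clusters_raw, cell_graph,
                                         min_size = cfg$merge$min_size))
  manifest$clustering <- list(
    n_clusters_mcl = length(unique(clusters_raw)),
    n_clusters_merged = length(unique(clusters)))
  logmsg("MCL: ", length(unique(clusters_raw)), " clusters -> ",
         length(unique(clusters)), " after merging")
  graph_cells <- names(clusters)
  stage_of <- stats::setNames(as.character(nm$stage), colnames(nm))
  write_cluster_table(clusters, stage_of,
                      file.path(outdir, "cell_clusters.tsv"))

  # ---- pseudobulk / GCN / Louvain ----
  nm_graph <- nm[, graph_cells]
  pb <- stage("pseudobulk", aggregate_by_cluster_stage(
    nm_graph, clusters, min_cells = cfg$pseudobulk$min_cells,
    min_max = cfg$pseudobulk$min_max, min_frac = cfg$pseudobulk$min_frac,
    percentile = cfg$pseudobulk$percentile,
    per_stage_filters = cfg$pseudobulk$per_stage_filters))
  manifest$pseudobulk <- list(
    n_columns = ncol(pb$profiles),
    n_mixed_stage_clusters = sum(table(pb$meta$cluster_id) > 1))
  write_pseudobulk(pb, file.path(outdir, "pseudobulk.tsv"))
  pb_f <- stage("gcn_filter",
                filter_low_expression_genes(pb, min_max = cfg$gcn$min_max))
  gene_graph <- stage("gene_graph",
                      build_gene_knn_graph(pb_f, k = cfg$gcn$k,
                                           r_min = cfg$gcn$r_min))
  gc <- stage("louvain", louvain_cluster(
    gene_graph, resolution = cfg$gcn$resolution, seed = child_seeds[3]))
  manifest$gcn <- list(n_genes = igraph::vcount(gene_graph),
                       n_edges = igraph::ecount(gene_graph),
                       n_gene_clusters = length(unique(gc$assignment)),
                       modularity = gc$modularity)
  logmsg("GCN: ", igraph::vcount(gene_graph), " genes, ",
         length(unique(gc$assignment)), " gene clusters")
  write_graph_file(gene_graph, file.path(outdir, "gene_graph.tsv"),
                   "edgelist")
  write_gene_clusters(gc, file.path(outdir, "gene_clusters.tsv"))
  utils::write.table(
    data.frame(profile = rownames(gene_cluster_profiles(pb_f, gc)),
               gene_cluster_profiles(pb_f, gc), check.names = FALSE),
    file.path(outdir, "gene_cluster_profiles.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- markers / enrichment ----
  markers <- NULL
  if (isTRUE(cfg$markers$enabled) && length(unique(clusters)) >= 2) {
    markers <- stage("markers", wilcoxon_markers(
      nm_graph, clusters, min_pct = cfg$markers$min_pct,
      logfc_min = cfg$markers$logfc_min,
      group_by_stage = cfg$markers$group_by_stage))
    manifest$markers <- list(n_records = nrow(markers),
                             n_significant = sum(markers$adj_p_value < 0.05))
    utils::write.table(markers, file.path(outdir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  enrichment <- NULL
  if (!is.null(cfg$enrich$gmt)) {
    enrichment <- stage("enrich", {
      sets <- read_gmt(cfg$enrich$gmt)
      genes_by_cluster <- split(names(gc$assignment), gc$assignment)
      universe <- names(gc$assignment)
      if (!is.null(cfg$enrich$homolog_map)) {
        map <- utils::read.table(cfg$enrich$homolog_map, sep = "\t",
                                 header = FALSE, stringsAsFactors = FALSE)
        universe <- map_homologs(universe, map)
        genes_by_cluster <- lapply(genes_by_cluster, map_homologs, map = map)
      }
      res <- lapply(names(genes_by_cluster), function(cl) {
        q <- genes_by_cluster[[cl]]
        if (!length(q)) return(NULL)
        cbind(gene_cluster = cl, ora_enrichment(q, sets, universe))
      })
      do.call(rbind, res)
    })
    manifest$enrichment <- list(n_tests = if (is.null(enrichment)) 0 else
      nrow(enrichment))
    if (!is.null(enrichment)) {
      utils::write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logmsg("pipeline complete: ", outdir)
  invisible(list(sce = nm, truth = truth, pca = pca,
                 cell_graph = cell_graph, clusters = clusters,
                 pseudobulk = pb, gene_graph = gene_graph,
                 gene_clusters = gc, markers = markers,
                 enrichment = enrichment, manifest = manifest))
}
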