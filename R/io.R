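#' Read a 10x-style count bundle
#'
#' Reads a sparse UMI count matrix in Matrix Market coordinate format
#' together with its feature and barcode tables, and returns a
#' [SingleCellExperiment::SingleCellExperiment] with genes as rows and cells
#' as columns. The on-disk orientation follows the 10x convention
#' (genes x cells). Plain and gzip-compressed files are both accepted.
#'
#' Mitochondrial genes are flagged from the gene *name* column by a regular
#' expression and/or from an explicit gene-ID list. There is no default
#' pattern: insect mitochondrial gene names do not follow the vertebrate
#' "MT-" prefix, so an unset pattern flags nothing rather than guessing.
#'
#' @param matrix_path Path to the Matrix Market (.mtx or .mtx.gz) file.
#' @param features_path Path to a TSV with columns gene_id, gene_name (no
#'   header). A one-column file is accepted; names are then copied from IDs.
#' @param barcodes_path Path to a text file with one cell barcode per line.
#' @param stage Character scalar; free-text sample/stage label attached to
#'   every cell of this bundle.
#' @param mito_pattern Regular expression matched against gene names to flag
#'   mitochondrial genes, or `NULL` to skip pattern matching.
#' @param mito_ids Character vector of gene IDs to flag as mitochondrial in
#'   addition to any pattern matches.
#' @return A `SingleCellExperiment` with a `counts` assay (dgCMatrix),
#'   `rowData` columns `gene_id`, `gene_name`, `mito`, and `colData` columns
#'   `barcode`, `stage`.
#' @export
read_count_bundle <- function(matrix_path, features_path, barcodes_path,
                              stage, mito_pattern = NULL, mito_ids = NULL) {
  for (p in c(matrix_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.table(features_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != nrow(feats)) {
    stop("dimension mismatch: matrix declares ", nrow(m), " genes but ",
         features_path, " has ", nrow(feats), " rows")
  }
  if (ncol(m) != length(barcodes)) {
    stop("dimension mismatch: matrix declares ", ncol(m), " cells but ",
         barcodes_path, " has ", length(barcodes), " barcodes")
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  vals <- m@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
    stop("counts in ", matrix_path, " must be non-negative integers")
  }
  gene_id <- as.character(feats[[1]])
  gene_name <- if (ncol(feats) >= 2) as.character(feats[[2]]) else gene_id
  if (anyDuplicated(gene_id)) stop("duplicate gene IDs in ", features_path)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in ", barcodes_path)
  mito <- rep(FALSE, length(gene_id))
  if (!is.null(mito_pattern)) mito <- mito | grepl(mito_pattern, gene_name)
  if (!is.null(mito_ids)) mito <- mito | gene_id %in% mito_ids
  dimnames(m) <- list(gene_id, barcodes)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(gene_id = gene_id, gene_name = gene_name,
                                   mito = mito, row.names = gene_id),
    colData = S4Vectors::DataFrame(barcode = barcodes,
                                   stage = rep(stage, length(barcodes)),
                                   row.names = barcodes))
}

#' Write a count matrix as a 10x-style bundle
#'
#' Inverse of [read_count_bundle()]: writes matrix.mtx, features.tsv and
#' barcodes.tsv (uncompressed) into `dir`.
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the paths of the three files written.
#' @export
write_count_bundle <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(SummarizedExperiment::assay(sce, "counts"),
                              "generalMatrix"), paths[1])
  rd <- SummarizedExperiment::rowData(sce)
  utils::write.table(data.frame(rd$gene_id, rd$gene_name), paths[2],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(colnames(sce), paths[3])
  invisible(paths)
}

#' Merge per-stage count matrices
#'
#' Concatenates the cells of several stage-labelled count matrices. The gene
#' set of the result is the union of the input gene sets, with counts for
#' genes absent from a bundle filled with zeros. Cell barcodes are made
#' unique by suffixing the stage label (`<barcode>-<stage>`); a collision
#' after suffixing is an error. Total UMI count is preserved.
#'
#' @param matrices A list of `SingleCellExperiment` objects as returned by
#'   [read_count_bundle()].
#' @return A merged `SingleCellExperiment`.
#' @export
merge_stages <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  gene_ids <- unique(unlist(lapply(matrices, rownames)))
  pieces <- vector("list", length(matrices))
  rd_all <- list()
  for (i in seq_along(matrices)) {
    sce <- matrices[[i]]
    cnt <- SummarizedExperiment::assay(sce, "counts")
    full <- Matrix::Matrix(0, nrow = length(gene_ids), ncol = ncol(cnt),
                           sparse = TRUE,
                           dimnames = list(gene_ids, colnames(cnt)))
    full[rownames(cnt), ] <- cnt
    colnames(full) <- paste0(colnames(cnt), "-", sce$stage)
    pieces[[i]] <- methods::as(full, "CsparseMatrix")
    rd_all[[i]] <- as.data.frame(SummarizedExperiment::rowData(sce))
  }
  merged <- do.call(cbind, pieces)
  if (anyDuplicated(colnames(merged))) {
    dup <- colnames(merged)[duplicated(colnames(merged))][1]
    stop("duplicate barcode after stage suffixing: ", dup)
  }
  rd <- do.call(rbind, rd_all)
  rd <- rd[!duplicated(rd$gene_id), , drop = FALSE]
  rownames(rd) <- rd$gene_id
  rd <- rd[gene_ids, , drop = FALSE]
  stage <- unlist(lapply(matrices, function(s) as.character(s$stage)))
  barcode <- unlist(lapply(matrices, colnames))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = merged),
    rowData = S4Vectors::DataFrame(rd, row.names = gene_ids),
    colData = S4Vectors::DataFrame(barcode = barcode, stage = stage,
                                   row.names = colnames(merged)))
}

#' Write a weighted graph to disk
#'
#' Supported formats: a three-column edge-list TSV (`source`, `target`,
#' `weight`, weights printed with 10 significant digits so a round trip
#' through [read_graph_file()] is exact to printed precision) and GraphML.
#' Isolated nodes are preserved in GraphML; the edge-list format records
#' them in a `#nodes:` comment line so round trips are lossless.
#'
#' @param graph An `igraph` object with an edge attribute `weight`.
#' @param path Output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_graph_file <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  w <- if (igraph::ecount(graph)) igraph::E(graph)$weight else numeric(0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#nodes: ",
                    paste(igraph::V(graph)$name, collapse = "\t")), con)
  writeLines("source\ttarget\tweight", con)
  if (nrow(el)) {
    writeLines(paste(el[, 1], el[, 2], formatC(w, digits = 10, format = "g"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a weighted graph written by [write_graph_file()]
#'
#' @param path File path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return An `igraph` object.
#' @export
read_graph_file <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path)
  nodes <- character(0)
  if (length(lines) && startsWith(lines[1], "#nodes:")) {
    node_str <- sub("^#nodes:[ ]?", "", lines[1])
    if (nzchar(node_str)) nodes <- strsplit(node_str, "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  stopifnot(length(lines) >= 1, lines[1] == "source\ttarget\tweight")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(lines) > 1) {
    df <- utils::read.table(text = lines[-1], sep = "\t", header = FALSE,
                            col.names = c("source", "target", "weight"),
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "numeric"))
    g <- igraph::add_edges(g, rbind(match(df$source, nodes),
                                    match(df$target, nodes)),
                           weight = df$weight)
  }
  g
}

#' Write a cell-cluster assignment table
#'
#' Writes a TSV with columns `barcode`, `stage`, `cluster_id`, rows ordered
#' lexicographically by barcode so output is deterministic.
#'
#' @param assignment Named integer vector mapping cell barcode to cluster ID.
#' @param stage Named character vector mapping cell barcode to stage label,
#'   or `NULL` to write `NA` stages.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cluster_table <- function(assignment, stage = NULL, path) {
  bc <- sort(names(assignment))
  df <- data.frame(barcode = bc,
                   stage = if (is.null(stage))
                     rep(NA_character_, length(bc)) else unname(stage[bc]),
                   cluster_id = unname(assignment[bc]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster table written by [write_cluster_table()]
#'
#' @param path File path.
#' @return A data frame with columns `barcode`, `stage`, `cluster_id`.
#' @export
read_cluster_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer"))
}
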