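#' Read a CellRanger-style MatrixMarket triplet
#'
#' Reads a coordinate MatrixMarket file of raw integer UMI counts together
#' with header-bearing gene and cell TSV tables, and returns a validated
#' \linkS4class{CrossSpeciesCounts} with cached per-cell depths. Row and
#' column order follow the tables; MTX indices are 1-based.
#'
#' @param matrix_path path to the \code{.mtx} file (genes x cells).
#' @param genes_path path to the gene table TSV (header required; first
#'   column or \code{gene_id} holds identifiers).
#' @param cells_path path to the cell table TSV (header required; must
#'   include a \code{species} column).
#' @return A \linkS4class{CrossSpeciesCounts}.
#' @export
readCountMatrix <- function(matrix_path, genes_path, cells_path) {
  for (p in c(matrix_path, genes_path, cells_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  CrossSpeciesCounts(m, genes, cells)
}

#' Write the MatrixMarket triplet for a CrossSpeciesCounts
#'
#' @param x a \linkS4class{CrossSpeciesCounts}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the three paths written.
#' @export
writeCountMatrix <- function(x, dir, prefix = "matrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, paste0(prefix, ".mtx"))
  gp <- file.path(dir, paste0(prefix, ".genes.tsv"))
  cp <- file.path(dir, paste0(prefix, ".cells.tsv"))
  Matrix::writeMM(SummarizedExperiment::assay(x, "counts"), mp)
  utils::write.table(as.data.frame(rowData(x)), gp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(colData(x))
  cd$depth <- NULL
  utils::write.table(cd, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mp, genes = gp, cells = cp))
}

#' Remove cells with too few UMIs
#'
#' Retains exactly the cells whose total UMI count (depth) is at least
#' \code{min_umi}; the default drops cells with fewer than 200 UMIs, the
#' usual floor for sparse combinatorial-indexing data. Gene set and cell
#' order are preserved.
#'
#' @param x a \linkS4class{CrossSpeciesCounts}.
#' @param min_umi minimum per-cell depth kept (cells with depth <
#'   \code{min_umi} are removed).
#' @return Filtered \linkS4class{CrossSpeciesCounts}.
#' @export
filterCellsMinUMI <- function(x, min_umi = 200) {
  stopifnot(min_umi >= 0)
  keep <- colData(x)$depth >= min_umi
  x[, keep]
}

#' Remove genes expressed in too few cells
#'
#' A gene is "expressed" in a cell when its raw count is > 0; genes
#' nonzero in fewer than \code{min_cells} cells (counted across the whole
#' matrix, i.e. across all concatenated datasets) are dropped and per-cell
#' depths are recomputed.
#'
#' @param x a \linkS4class{CrossSpeciesCounts}.
#' @param min_cells minimum number of cells with a nonzero count.
#' @return Filtered \linkS4class{CrossSpeciesCounts}.
#' @export
filterGenesMinCells <- function(x, min_cells = 50) {
  stopifnot(min_cells >= 0)
  m <- SummarizedExperiment::assay(x, "counts")
  ncells <- Matrix::rowSums(m > 0)
  .recomputeDepth(x[ncells >= min_cells, ])
}

#' Drop a named set of genes
#'
#' Removes the listed genes (e.g. mitochondrial genes) and recomputes the
#' cached depths. Identifiers not present in the matrix are ignored with a
#' warning.
#'
#' @param x a \linkS4class{CrossSpeciesCounts}.
#' @param gene_ids character vector of gene identifiers to drop.
#' @return Filtered \linkS4class{CrossSpeciesCounts}.
#' @export
removeGeneSet <- function(x, gene_ids) {
  gene_ids <- as.character(gene_ids)
  unknown <- setdiff(gene_ids, rownames(x))
  if (length(unknown))
    warning(length(unknown), " gene id(s) not present, ignored: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  keep <- !(rownames(x) %in% gene_ids)
  .recomputeDepth(x[keep, ])
}

#' Keep only genes covered by a one-to-one ortholog map
#'
#' Subsets to the genes listed for the given species in an
#' \linkS4class{OneToOneMap} (hub column when \code{species} is the hub).
#'
#' @param x a \linkS4class{CrossSpeciesCounts}.
#' @param map a \linkS4class{OneToOneMap}.
#' @param species which species' gene ids the matrix rows use.
#' @return Filtered \linkS4class{CrossSpeciesCounts}.
#' @export
keepOrthologGenes <- function(x, map, species) {
  tb <- map@table
  ids <- if (species == map@hub_species) tb$hub else tb[[species]]
  if (is.null(ids)) stop("species '", species, "' not in the ortholog map")
  .recomputeDepth(x[rownames(x) %in% ids[!is.na(ids)], ])
}

#' Depth-normalize a count matrix
#'
#' Scales every cell (column) so that its counts sum to \code{target}.
#'
#' @param x a \linkS4class{CrossSpeciesCounts} or a numeric matrix of
#'   counts (genes x cells).
#' @param target per-cell total after normalization (10,000 by default,
#'   the conventional library size; use 1 for relative abundances).
#' @return A sparse or dense real matrix of the same shape.
#' @export
depthNormalize <- function(x, target = 10000) {
  m <- if (methods::is(x, "CrossSpeciesCounts"))
    SummarizedExperiment::assay(x, "counts") else x
  d <- Matrix::colSums(m)
  if (any(d <= 0)) {
    bad <- colnames(m)[d <= 0]
    if (is.null(bad)) bad <- which(d <= 0)
    stop("zero-depth cell(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (methods::is(m, "sparseMatrix")) {
    m %*% Matrix::Diagonal(x = target / d, names = FALSE) -> out
    dimnames(out) <- dimnames(m)
    out
  } else {
    sweep(m, 2, target / d, "*")
  }
}

#' Pseudobulk profiles by cell group
#'
#' Averages sequencing-depth-normalized expression across the cells of
#' each group; optionally log2(x + 1)-transforms the averaged profile.
#' The log transform is applied after averaging, so a pseudobulk value of
#' 3 becomes log2(4) = 2.
#'
#' @param x a \linkS4class{CrossSpeciesCounts}.
#' @param group_by character vector of \code{colData} columns defining the
#'   groups (e.g. \code{c("cell_type", "species")}).
#' @param log_transform apply \code{log2(value + 1)} after averaging.
#' @param target depth-normalization target passed to
#'   \code{\link{depthNormalize}} (default 1: relative abundances).
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"pseudobulk"} (genes x groups), group keys and \code{n_cells}
#'   in \code{colData}, and \code{log_transformed} in the metadata.
#' @export
pseudobulk <- function(x, group_by, log_transform = FALSE, target = 1) {
  cd <- as.data.frame(colData(x))
  missing_keys <- setdiff(group_by, colnames(cd))
  if (length(missing_keys))
    stop("grouping key(s) not in cell table: ",
         paste(missing_keys, collapse = ", "))
  norm <- depthNormalize(x, target = target)
  key <- interaction(cd[group_by], drop = TRUE, sep = ".", lex.order = TRUE)
  groups <- levels(key)
  prof <- matrix(0, nrow(x), length(groups),
                 dimnames = list(rownames(x), groups))
  n_cells <- integer(length(groups))
  for (i in seq_along(groups)) {
    idx <- which(key == groups[i])
    n_cells[i] <- length(idx)
    prof[, i] <- Matrix::rowSums(norm[, idx, drop = FALSE]) / length(idx)
  }
  if (log_transform) prof <- log2(prof + 1)
  meta <- unique(cd[group_by])
  meta <- meta[match(groups, do.call(paste,
                                     c(meta[group_by], sep = "."))), ,
               drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(pseudobulk = prof),
    colData = DataFrame(meta, n_cells = n_cells, row.names = groups))
  metadata(se)$log_transformed <- log_transform
  metadata(se)$target <- target
  se
}
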