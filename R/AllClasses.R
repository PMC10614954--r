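#' @import methods
#' @importFrom Matrix colSums rowSums t readMM writeMM sparseMatrix
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assays colData rowData colData<-
#'   SummarizedExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Gene-by-cell UMI count container
#'
#' Extends \linkS4class{SingleCellExperiment} with the invariants the
#' cross-species workflow relies on: a raw integer \code{counts} assay,
#' unique gene and cell identifiers, a \code{species} column in the cell
#' table, and a cached per-cell sequencing depth (\code{depth} in
#' \code{colData}) that always equals the column sums.
#'
#' @slot int_elementMetadata,int_colData inherited from
#'   \linkS4class{SingleCellExperiment}.
#' @export
setClass("CrossSpeciesCounts", contains = "SingleCellExperiment")

.validCrossSpeciesCounts <- function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is missing")
  m <- SummarizedExperiment::assay(object, "counts")
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(vals) && any(vals < 0))
    msg <- c(msg, "counts contain negative values")
  if (length(vals) && any(vals != round(vals)))
    msg <- c(msg, "counts contain non-integer values")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "cell ids must be present and unique")
  if (!"species" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'species' column")
  if (!"depth" %in% colnames(colData(object))) {
    msg <- c(msg, "colData must contain the cached 'depth' column")
  } else if (!isTRUE(all.equal(unname(colData(object)$depth),
                               unname(Matrix::colSums(m)),
                               tolerance = 1e-8))) {
    msg <- c(msg, "cached depth does not match column sums")
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("CrossSpeciesCounts", .validCrossSpeciesCounts)

#' Construct a CrossSpeciesCounts object
#'
#' @param counts gene-by-cell matrix of raw UMI counts (dense or any
#'   \pkg{Matrix} sparse form); entries must be non-negative integers.
#' @param genes \code{data.frame} of per-gene annotation; the first column
#'   (or a column named \code{gene_id}) holds unique gene identifiers.
#' @param cells \code{data.frame} of per-cell annotation with unique
#'   identifiers in the first column (or \code{cell_id}) and at least a
#'   \code{species} column; \code{batch}, \code{tissue}, \code{donor} and
#'   \code{cell_type} are used downstream when present.
#'
#' @return A \linkS4class{CrossSpeciesCounts} object with per-cell depth
#'   cached in \code{colData(x)$depth}.
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(5, 3),
#'                           dims = c(3, 2))
#' genes <- data.frame(gene_id = c("g1", "g2", "g3"))
#' cells <- data.frame(cell_id = c("c1", "c2"), species = "mouse")
#' cse <- CrossSpeciesCounts(m, genes, cells)
#' cellDepths(cse)
#' @export
CrossSpeciesCounts <- function(counts, genes, cells) {
  genes <- as.data.frame(genes)
  cells <- as.data.frame(cells)
  gid_col <- if ("gene_id" %in% colnames(genes)) "gene_id" else colnames(genes)[1]
  cid_col <- if ("cell_id" %in% colnames(cells)) "cell_id" else colnames(cells)[1]
  gid <- as.character(genes[[gid_col]])
  cid <- as.character(cells[[cid_col]])
  if (anyDuplicated(gid)) stop("duplicate gene ids")
  if (anyDuplicated(cid)) stop("duplicate cell ids")
  if (nrow(genes) != nrow(counts))
    stop("dimension mismatch: ", nrow(counts), " matrix rows vs ",
         nrow(genes), " gene-table rows")
  if (nrow(cells) != ncol(counts))
    stop("dimension mismatch: ", ncol(counts), " matrix columns vs ",
         nrow(cells), " cell-table rows")
  if (!"species" %in% colnames(cells))
    stop("cell table must contain a 'species' column")
  if (methods::is(counts, "Matrix")) {
    counts <- methods::as(counts, "CsparseMatrix")
  }
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(vals) && any(vals < 0)) stop("negative counts")
  if (length(vals) && any(vals != round(vals))) stop("non-integer counts")
  dimnames(counts) <- list(gid, cid)
  cells$depth <- unname(Matrix::colSums(counts))
  sce <- SingleCellExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(genes, row.names = gid),
    colData = DataFrame(cells, row.names = cid))
  methods::new("CrossSpeciesCounts", sce)
}

## Recompute the cached depth after any gene subsetting.
.recomputeDepth <- function(x) {
  colData(x)$depth <- unname(Matrix::colSums(SummarizedExperiment::assay(x, "counts")))
  x
}

#' @rdname CrossSpeciesCounts
#' @param x a \code{CrossSpeciesCounts} object
#' @export
setGeneric("cellDepths", function(x) standardGeneric("cellDepths"))

#' @rdname CrossSpeciesCounts
#' @export
setMethod("cellDepths", "CrossSpeciesCounts", function(x) {
  stats::setNames(colData(x)$depth, colnames(x))
})

#' @rdname CrossSpeciesCounts
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname CrossSpeciesCounts
#' @export
setMethod("speciesLabels", "CrossSpeciesCounts", function(x) {
  stats::setNames(as.character(colData(x)$species), colnames(x))
})

setMethod("show", "CrossSpeciesCounts", function(object) {
  cat("CrossSpeciesCounts:", nrow(object), "genes x", ncol(object), "cells\n")
  sp <- table(colData(object)$species)
  cat("species:", paste(names(sp), sp, sep = "=", collapse = ", "), "\n")
  cat("median depth:", stats::median(colData(object)$depth), "\n")
})

#' Many-to-many cross-species orthology graph
#'
#' Undirected graph whose vertices are species-labelled genes and whose
#' edges carry a percent-identity score. Same-species edges and self-edges
#' are forbidden; scores live in [0, 100].
#'
#' @slot edges \code{data.frame} with columns \code{gene_a},
#'   \code{species_a}, \code{gene_b}, \code{species_b},
#'   \code{percent_identity}.
#' @export
setClass("OrthologGraph", representation(edges = "data.frame"))

.validOrthologGraph <- function(object) {
  e <- object@edges
  need <- c("gene_a", "species_a", "gene_b", "species_b", "percent_identity")
  if (!all(need %in% colnames(e)))
    return(paste("edge table must have columns:", paste(need, collapse = ", ")))
  msg <- NULL
  if (nrow(e)) {
    if (any(e$species_a == e$species_b))
      msg <- c(msg, "edges within one species are not allowed")
    if (any(e$gene_a == e$gene_b & e$species_a == e$species_b))
      msg <- c(msg, "self-edges are not allowed")
    if (any(e$percent_identity < 0 | e$percent_identity > 100))
      msg <- c(msg, "percent identity must be in [0, 100]")
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("OrthologGraph", .validOrthologGraph)

#' Construct an OrthologGraph
#'
#' @param edges \code{data.frame} with columns \code{gene_a},
#'   \code{species_a}, \code{gene_b}, \code{species_b},
#'   \code{percent_identity} (one row per orthology edge; direction is
#'   ignored).
#' @return An \linkS4class{OrthologGraph}.
#' @export
OrthologGraph <- function(edges) {
  edges <- as.data.frame(edges)
  for (cc in c("gene_a", "species_a", "gene_b", "species_b"))
    if (cc %in% colnames(edges)) edges[[cc]] <- as.character(edges[[cc]])
  methods::new("OrthologGraph", edges = edges)
}

setMethod("show", "OrthologGraph", function(object) {
  sp <- unique(c(object@edges$species_a, object@edges$species_b))
  cat("OrthologGraph:", nrow(object@edges), "edges among",
      length(sp), "species (", paste(sp, collapse = ", "), ")\n")
})

#' @rdname OrthologGraph
#' @param x an \code{OrthologGraph}
#' @export
setGeneric("orthologEdges", function(x) standardGeneric("orthologEdges"))

#' @rdname OrthologGraph
#' @export
setMethod("orthologEdges", "OrthologGraph", function(x) x@edges)

#' One-to-one cross-species gene map
#'
#' Result of reconciling a many-to-many orthology graph: one row per hub
#' gene, one column per species, each gene appearing at most once, plus a
#' per-species provenance marker (\code{"direct"} or \code{"transitive"}).
#'
#' @slot hub_species species whose genes index the rows.
#' @slot table \code{data.frame}: column \code{hub} plus one column per
#'   non-hub species (NA where no ortholog).
#' @slot provenance \code{data.frame} parallel to the non-hub columns of
#'   \code{table}.
#' @export
setClass("OneToOneMap",
         representation(hub_species = "character",
                        table = "data.frame",
                        provenance = "data.frame"))

.validOneToOneMap <- function(object) {
  tb <- object@table
  msg <- NULL
  if (!"hub" %in% colnames(tb)) return("table must contain a 'hub' column")
  if (anyDuplicated(tb$hub)) msg <- c(msg, "hub genes must be unique")
  for (cc in setdiff(colnames(tb), "hub")) {
    v <- tb[[cc]]
    v <- v[!is.na(v)]
    if (anyDuplicated(v))
      msg <- c(msg, paste0("species '", cc, "' gene mapped to >1 hub gene"))
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("OneToOneMap", .validOneToOneMap)

setMethod("show", "OneToOneMap", function(object) {
  prov <- as.matrix(object@provenance)
  cat("OneToOneMap (hub:", object@hub_species, "):",
      nrow(object@table), "hub genes;",
      sum(prov == "direct", na.rm = TRUE), "direct and",
      sum(prov == "transitive", na.rm = TRUE), "transitive edges\n")
})

#' Flatten a OneToOneMap to a data.frame
#'
#' @param x a \linkS4class{OneToOneMap}
#' @return the row table with per-species provenance columns appended.
#' @export
setGeneric("orthologTable", function(x) standardGeneric("orthologTable"))

#' @rdname orthologTable
#' @export
setMethod("orthologTable", "OneToOneMap", function(x) {
  cbind(x@table,
        stats::setNames(x@provenance,
                        paste0("provenance_", colnames(x@provenance))))
})

#' Conditional VAE model for cross-species expression
#'
#' Holds the encoder/decoder/discriminator parameters, the factor-level
#' dictionaries (species/batch/tissue label to one-hot index), the model
#' configuration, and the training history once fitted.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot config named list, see \code{\link{cvaeConfig}}.
#' @slot levels list with character vectors \code{species}, \code{batch},
#'   \code{tissue}.
#' @slot dims list with \code{n_genes}, \code{n_latent}, \code{hidden_width}.
#' @slot history list: per-epoch losses, \code{best_epoch},
#'   \code{best_val_loss}, \code{lisi_score} when computed.
#' @export
setClass("CVAEModel",
         representation(params = "list", config = "list", levels = "list",
                        dims = "list", history = "list"))

setMethod("show", "CVAEModel", function(object) {
  d <- object@dims
  cat("CVAEModel:", d$n_genes, "genes ->", d$n_latent, "latent dims",
      sprintf("(2 hidden layers x %d units)", d$hidden_width), "\n")
  cat("species levels:", paste(object@levels$species, collapse = ", "), "\n")
  cat("discriminator:", if (isTRUE(object@config$use_discriminator)) "on" else "off", "\n")
  if (length(object@history)) {
    cat("trained:", object@history$best_epoch, "best epoch, val loss",
        signif(object@history$best_val_loss, 6), "\n")
  } else cat("untrained\n")
})
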