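#' Genes-by-cells expression matrix container
#'
#' `expr_matrix()` wraps a genes x cells matrix (dense or sparse) together
#' with gene and cell identifiers and a layer tag recording what the values
#' are: raw `"counts"`, library-size log-normalized `"lognorm"`, or centered
#' log-ratio `"clr"`. All package functions that consume expression data take
#' this container.
#'
#' Identifiers must be unique. Duplicate gene symbols coming out of
#' [read_10x_mtx()] are disambiguated by suffixing (`GENE`, `GENE.1`, ...)
#' before construction. Counts layers must be non-negative and integral;
#' every layer must be finite.
#'
#' @param values numeric matrix or `Matrix::sparseMatrix`, genes in rows and
#'   cells in columns.
#' @param gene_ids character vector of row identifiers; defaults to existing
#'   rownames.
#' @param cell_ids character vector of column identifiers; defaults to
#'   existing colnames.
#' @param layer one of `"counts"`, `"lognorm"`, `"clr"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (a `dgCMatrix` with dimnames) and `layer`.
#' @examples
#' m <- expr_matrix(matrix(rpois(12, 4), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("c", 1:4))))
#' m
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        cell_ids = colnames(values), layer = "counts") {
  layer <- match.arg(layer, c("counts", "lognorm", "clr"))
  if (is.null(gene_ids)) gene_ids <- paste0("gene-", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell-", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("`gene_ids` length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")", call. = FALSE)
  if (length(cell_ids) != ncol(values))
    stop("`cell_ids` length (", length(cell_ids), ") != number of columns (",
         ncol(values), ")", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids: ",
         paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 5),
               collapse = ", "), call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one gene and one cell",
         call. = FALSE)
  v <- Matrix::Matrix(values, sparse = TRUE)
  v <- methods::as(methods::as(methods::as(v, "dMatrix"),
                               "generalMatrix"), "CsparseMatrix")
  if (any(!is.finite(v@x)))
    stop("expression values must be finite", call. = FALSE)
  if (layer == "counts" && length(v@x) &&
      (any(v@x < 0) || any(v@x != round(v@x))))
    stop("counts layer must contain non-negative integers", call. = FALSE)
  dimnames(v) <- list(gene_ids, cell_ids)
  structure(list(values = v, layer = layer), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells, layer = ", x$layer,
      sprintf(" (%.1f%% nonzero)\n",
              100 * length(x$values@x) / prod(dim(x$values))), sep = "")
  invisible(x)
}

#' Gene and cell identifiers
#'
#' @param m an [expr_matrix()].
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(m) colnames(m$values)

#' Subset an expression matrix
#'
#' Restrict to a set of genes and/or cells, by identifier or index, keeping
#' the layer tag.
#'
#' @param m an [expr_matrix()].
#' @param genes,cells identifiers or indices to keep; `NULL` keeps all.
#' @return An [expr_matrix()].
#' @export
subset_expr <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  if (!is.null(genes)) {
    if (is.character(genes)) {
      missing <- setdiff(genes, rownames(v))
      if (length(missing))
        stop("genes not present: ", paste(utils::head(missing, 5),
                                          collapse = ", "), call. = FALSE)
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(cells)) {
    if (is.character(cells)) {
      missing <- setdiff(cells, colnames(v))
      if (length(missing))
        stop("cells not present: ", paste(utils::head(missing, 5),
                                          collapse = ", "), call. = FALSE)
    }
    v <- v[, cells, drop = FALSE]
  }
  expr_matrix(v, layer = m$layer)
}

# Align a cluster assignment to the cells of `m`, returning a factor named
# by cell_id. Accepts a data frame with columns cell_id + cluster, or a
# named vector/factor. Every cell must be labelled exactly once and every
# cluster must be non-empty (guaranteed by construction from droplevels).
align_clusters <- function(clusters, m) {
  ids <- cell_ids(m)
  if (is.data.frame(clusters)) {
    if (!all(c("cell_id", "cluster") %in% names(clusters)))
      stop("cluster data frame needs columns `cell_id` and `cluster`",
           call. = FALSE)
    lab <- stats::setNames(as.character(clusters$cluster),
                           as.character(clusters$cell_id))
  } else if (!is.null(names(clusters))) {
    lab <- stats::setNames(as.character(clusters), names(clusters))
  } else if (length(clusters) == length(ids)) {
    lab <- stats::setNames(as.character(clusters), ids)
  } else {
    stop("clusters must be a cell_id/cluster data frame, a named vector, ",
         "or an unnamed vector with one label per cell", call. = FALSE)
  }
  if (anyDuplicated(names(lab)))
    stop("duplicate cell_id in cluster assignment", call. = FALSE)
  unlabelled <- setdiff(ids, names(lab))
  if (length(unlabelled))
    stop("cells without a cluster label: ",
         paste(utils::head(unlabelled, 5), collapse = ", "), call. = FALSE)
  droplevels(factor(lab[ids]))
}

#' Cluster assignment as a tibble
#'
#' Normalizes any accepted cluster-label representation (tibble, named
#' vector, plain vector aligned to the matrix columns) into the canonical
#' two-column tibble used throughout.
#'
#' @param clusters labels: a data frame with columns `cell_id`, `cluster`; a
#'   vector named by cell id; or an unnamed vector aligned to `cell_ids(m)`.
#' @param m the [expr_matrix()] the labels refer to.
#' @return A tibble with columns `cell_id`, `cluster` (factor).
#' @export
cluster_tbl <- function(clusters, m) {
  f <- align_clusters(clusters, m)
  tibble::tibble(cell_id = cell_ids(m), cluster = f)
}
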