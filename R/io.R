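#' Read a 10x Genomics MTX triplet directory
#'
#' Loads `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or the legacy
#' `genes.tsv`), each optionally gzipped, from a CellRanger-style directory
#' into an [expr_matrix()] with genes as rows and cells as columns. The
#' 1-based MatrixMarket coordinates are handled by the reader; duplicated
#' gene symbols are made unique by suffixing so identifiers are usable as
#' keys.
#'
#' @param dir_path directory containing the triplet.
#' @param gene_column which column of the feature table to use as gene
#'   identifier (CellRanger features.tsv has id, symbol, type; default 2 =
#'   symbol, falling back to column 1 for single-column files).
#' @return An [expr_matrix()] with `layer = "counts"`.
#' @export
read_10x_mtx <- function(dir_path, gene_column = 2L) {
  locate <- function(stems) {
    for (stem in stems) for (ext in c("", ".gz")) {
      p <- file.path(dir_path, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    stop("no file ", paste(stems, collapse = " / "), " (or .gz) in ",
         dir_path, call. = FALSE)
  }
  mtx_file <- locate("matrix.mtx")
  bc_file <- locate("barcodes.tsv")
  ft_file <- locate(c("features.tsv", "genes.tsv"))

  counts <- methods::as(Matrix::readMM(mtx_file), "CsparseMatrix")
  barcodes <- readr::read_tsv(bc_file, col_names = FALSE,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)[[1]]
  features <- readr::read_tsv(ft_file, col_names = FALSE,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  gcol <- min(gene_column, ncol(features))
  genes <- features[[gcol]]
  if (length(barcodes) != ncol(counts))
    stop("matrix has ", ncol(counts), " columns but ", length(barcodes),
         " barcodes", call. = FALSE)
  if (length(genes) != nrow(counts))
    stop("matrix has ", nrow(counts), " rows but ", length(genes),
         " features", call. = FALSE)
  expr_matrix(counts, gene_ids = make.unique(genes), cell_ids = barcodes,
              layer = "counts")
}

#' Write a 10x-style MTX triplet
#'
#' Inverse of [read_10x_mtx()]: writes `matrix.mtx`, `barcodes.tsv` and
#' `features.tsv` (id and symbol columns both set to the gene id) so the
#' directory can be read back losslessly.
#'
#' @param m an [expr_matrix()].
#' @param dir_path output directory, created if needed.
#' @return `dir_path`, invisibly.
#' @export
write_10x_mtx <- function(m, dir_path) {
  stopifnot(inherits(m, "expr_matrix"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$values, file.path(dir_path, "matrix.mtx"))
  writeLines(cell_ids(m), file.path(dir_path, "barcodes.tsv"))
  readr::write_tsv(
    tibble::tibble(id = gene_ids(m), symbol = gene_ids(m),
                   type = "Gene Expression"),
    file.path(dir_path, "features.tsv"), col_names = FALSE, progress = FALSE)
  invisible(dir_path)
}

#' Read and write cell-level label tables
#'
#' `read_labels_tsv()` reads a two-column `cell_id<TAB>cluster` file (no
#' header) into the canonical cluster tibble; `write_labels_tsv()` writes
#' one. `read_embedding_tsv()` reads `cell_id<TAB>x<TAB>y` coordinates into
#' the embedding tibble used by the hull-trimming functions.
#'
#' @param path file path.
#' @return A tibble (`cell_id`, `cluster`) or (`cell_id`, `x`, `y`).
#' @export
read_labels_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("cell_id", "cluster"),
                  col_types = "cc", progress = FALSE)
}

#' @rdname read_labels_tsv
#' @param labels a tibble with columns `cell_id`, `cluster`.
#' @export
write_labels_tsv <- function(labels, path) {
  readr::write_tsv(labels[, c("cell_id", "cluster")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname read_labels_tsv
#' @export
read_embedding_tsv <- function(path) {
  emb <- readr::read_tsv(path, col_names = c("cell_id", "x", "y"),
                         col_types = "cdd", progress = FALSE)
  if (any(!is.finite(emb$x)) || any(!is.finite(emb$y)))
    stop("embedding coordinates must be finite", call. = FALSE)
  emb
}

# Align an embedding (tibble cell_id/x/y or bare n x 2 matrix) to cell ids,
# returning an n x 2 matrix with rownames.
align_embedding <- function(emb, ids) {
  if (is.data.frame(emb)) {
    stopifnot(all(c("cell_id", "x", "y") %in% names(emb)))
    missing <- setdiff(ids, emb$cell_id)
    if (length(missing))
      stop("cells missing from embedding: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    xy <- as.matrix(emb[match(ids, emb$cell_id), c("x", "y")])
  } else {
    xy <- as.matrix(emb)
    if (ncol(xy) != 2L) stop("embedding must have two columns", call. = FALSE)
    if (is.null(rownames(xy))) {
      if (nrow(xy) != length(ids))
        stop("embedding rows do not match cells", call. = FALSE)
    } else {
      missing <- setdiff(ids, rownames(xy))
      if (length(missing))
        stop("cells missing from embedding: ",
             paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
      xy <- xy[ids, , drop = FALSE]
    }
  }
  if (any(!is.finite(xy)))
    stop("embedding coordinates must be finite", call. = FALSE)
  rownames(xy) <- ids
  colnames(xy) <- c("x", "y")
  xy
}
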