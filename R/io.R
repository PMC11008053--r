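#' Write a UMI count matrix as MatrixMarket + TSV
#'
#' Standard exchange trio: `matrix.mtx` (coordinate format, 1-based),
#' `genes.tsv` (gene id + mitochondrial flag) and `cells.tsv` (cell id +
#' any annotation columns supplied).
#'
#' @param counts genes x cells matrix (base or `Matrix` sparse).
#' @param dir Output directory.
#' @param genes Optional data.frame of gene annotations (first column must
#'   match `rownames(counts)`); defaults to the rownames.
#' @param cells Optional data.frame of cell annotations (first column must
#'   match `colnames(counts)`); defaults to the colnames.
#' @return Invisibly, the directory.
#' @export
write_counts_mtx <- function(counts, dir, genes = NULL, cells = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  if (is.null(genes))
    genes <- data.frame(gene = rownames(counts), stringsAsFactors = FALSE)
  if (is.null(cells))
    cells <- data.frame(cell = colnames(counts), stringsAsFactors = FALSE)
  stopifnot(identical(as.character(genes[[1]]), rownames(counts)),
            identical(as.character(cells[[1]]), colnames(counts)))
  write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a UMI count matrix written by [write_counts_mtx()]
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return List with `counts` (dgCMatrix with dimnames), `genes` and
#'   `cells` annotation data.frames.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- read.table(file.path(dir, "genes.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  cells <- read.table(file.path(dir, "cells.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  stopifnot(nrow(genes) == nrow(m), nrow(cells) == ncol(m))
  dimnames(m) <- list(as.character(genes[[1]]), as.character(cells[[1]]))
  list(counts = methods::as(m, "CsparseMatrix"), genes = genes, cells = cells)
}
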