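#' Cell-by-gene expression dataset
#'
#' A light container for a cells x genes count (or transformed) matrix
#' with gene identifiers, per-cell metadata and an explicit
#' processing-stage flag. Stages advance `raw -> normalized -> scaled`;
#' each pipeline step checks the stage of its input and returns a new
#' object, so raw counts are never mutated in place.
#'
#' @param counts A cells x genes matrix (dense or `Matrix` sparse). Raw
#'   matrices must contain nonnegative integers.
#' @param gene_ids Character vector of gene identifiers (columns).
#' @param cell_meta Data frame of per-cell metadata; a `cell` id column
#'   is added when absent. Typical columns: `dataset`, `replicate`,
#'   `true_state`.
#' @param stage One of `"raw"`, `"normalized"`, `"scaled"`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(counts, gene_ids = colnames(counts),
                               cell_meta = NULL, stage = "raw") {
  if (!stage %in% c("raw", "normalized", "scaled"))
    stop("'stage' must be raw, normalized or scaled", call. = FALSE)
  if (is.null(gene_ids))
    gene_ids <- sprintf("gene%04d", seq_len(ncol(counts)))
  stopifnot(length(gene_ids) == ncol(counts))
  if (is.null(cell_meta))
    cell_meta <- data.frame(cell = sprintf("cell%05d", seq_len(nrow(counts))),
                            stringsAsFactors = FALSE)
  if (is.null(cell_meta$cell))
    cell_meta$cell <- sprintf("cell%05d", seq_len(nrow(counts)))
  stopifnot(nrow(cell_meta) == nrow(counts))
  if (stage == "raw") {
    v <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
    if (length(v) && (min(v) < 0 || any(v != round(v))))
      stop("raw counts must be nonnegative integers", call. = FALSE)
  }
  colnames(counts) <- gene_ids
  rownames(counts) <- cell_meta$cell
  structure(list(matrix = counts, gene_ids = as.character(gene_ids),
                 cell_meta = cell_meta, stage = stage),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d cells x %d genes, stage: %s\n",
              nrow(x$matrix), ncol(x$matrix), x$stage))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

.check_stage <- function(ds, stage, op) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$stage != stage)
    stop(sprintf("%s() expects a dataset at stage '%s' (got '%s')",
                 op, stage, ds$stage), call. = FALSE)
  invisible(ds)
}

#' Write an expression dataset as Matrix Market plus TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells, the usual on-disk orientation),
#' `genes.tsv` and `cells.tsv` (tab-separated cell metadata with a
#' header) to `dir`.
#'
#' @param ds An `expression_dataset`.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_expression_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(
    Matrix::t(Matrix::Matrix(ds$matrix, sparse = TRUE)),
    "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$gene_ids, file.path(dir, "genes.tsv"))
  utils::write.table(ds$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an expression dataset written by [write_expression_dataset()]
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`,
#'   `cells.tsv`.
#' @param stage Stage flag to assign (`"raw"` by default).
#' @return An `expression_dataset`.
#' @export
read_expression_dataset <- function(dir, stage = "raw") {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  expression_dataset(methods::as(Matrix::t(m), "CsparseMatrix"),
                     gene_ids = genes, cell_meta = cells, stage = stage)
}
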