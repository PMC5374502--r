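#' @include AllClasses.R
NULL

.readTSV <- function(path) {
  if (!file.exists(path))
    stopc("scmge_missing_file", "file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a count matrix bundle
#'
#' Reads a genes x cells count matrix either from Matrix Market
#' coordinate format (`.mtx`, 1-based indices, integer field) or from a
#' TSV with genes as rows (first column = gene ids, header = cell ids),
#' together with its TSV gene-annotation and cell-metadata tables, and
#' returns a validated [ScCounts] object.  Matrix row/column order must
#' agree with the annotation tables; mismatches fail loudly.
#'
#' @param path matrix file (`.mtx` or `.tsv`).
#' @param genes_path TSV with header `gene_id`, `symbol`, `length_bp`,
#'   `is_mitochondrial`.
#' @param cells_path TSV with header `cell_id`, `condition`,
#'   `total_mapped_reads`.
#' @param unit count unit, `"reads"` or `"molecules"`.
#' @return An [ScCounts] object.
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path, genes_path, cells_path,
                            unit = c("reads", "molecules")) {
  unit <- match.arg(unit)
  genes <- .readTSV(genes_path)
  cells <- .readTSV(cells_path)
  for (col in c("gene_id", "symbol", "length_bp", "is_mitochondrial"))
    if (!col %in% names(genes))
      stopc("scmge_bad_annotation", "gene table lacks column '%s'", col)
  for (col in c("cell_id", "condition", "total_mapped_reads"))
    if (!col %in% names(cells))
      stopc("scmge_bad_annotation", "cell table lacks column '%s'", col)
  if (anyDuplicated(genes$gene_id))
    stopc("scmge_duplicate_id", "duplicated gene_id in %s", genes_path)
  if (anyDuplicated(cells$cell_id))
    stopc("scmge_duplicate_id", "duplicated cell_id in %s", cells_path)
  if (!file.exists(path))
    stopc("scmge_missing_file", "file not found: %s", path)

  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.logical(m)) storage.mode(m) <- "double"  # pattern dialect
  } else {
    raw <- .readTSV(path)
    ids <- as.character(raw[[1L]])
    m <- as.matrix(raw[, -1L, drop = FALSE])
    rownames(m) <- ids
    if (anyDuplicated(ids))
      stopc("scmge_duplicate_id", "duplicated gene_id in matrix %s", path)
    if (!identical(ids, as.character(genes$gene_id)))
      stopc("scmge_dim_mismatch",
            "matrix gene ids do not match the gene table order")
    if (!identical(colnames(m), as.character(cells$cell_id)))
      stopc("scmge_dim_mismatch",
            "matrix cell ids do not match the cell table order")
  }
  if (nrow(m) != nrow(genes) || ncol(m) != nrow(cells))
    stopc("scmge_dim_mismatch",
          "matrix is %d x %d but annotations describe %d genes x %d cells",
          nrow(m), ncol(m), nrow(genes), nrow(cells))
  if (!is.numeric(m) || anyNA(m) || !.isWholeNumber(m))
    stopc("scmge_noninteger", "count matrix entries must be non-negative integers")
  if (any(m < 0))
    stopc("scmge_noninteger", "count matrix entries must be non-negative integers")
  ScCounts(m, genes, cells, unit = unit)
}

#' Write a count matrix bundle
#'
#' Writes an [ScCounts] object as `matrix.mtx` (Matrix Market
#' coordinate, 1-based) plus `genes.tsv` and `cells.tsv` in `dir`, the
#' layout [readCountMatrix()] reads back.
#'
#' @param sc an [ScCounts] object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
writeCountMatrix <- function(sc, dir) {
  stopifnot(methods::is(sc, "ScCounts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  sp <- Matrix::Matrix(counts(sc), sparse = TRUE)
  sp <- methods::as(methods::as(sp, "dMatrix"), "generalMatrix")
  Matrix::writeMM(sp, paths[1L])
  utils::write.table(geneData(sc), paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cellData(sc), paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

.writeDF <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopc("scmge_unwritable", "cannot write to %s", path)
  invisible(path)
}

#' Write result tables as TSV
#'
#' TSV writers for the pipeline's result objects.  Numeric values are
#' written at full double precision so that reading the file back
#' reproduces ids exactly and values to within 1e-12 relative error.
#'
#' @param object a result object (`DEResult`, `MarkerSet`, `ScExpr`,
#'   `CellTypeCall`, `DataFrame` or `data.frame`).
#' @param path output file path.
#' @param ... unused.
#' @return Invisibly, `path`.
#' @name writeTable
NULL

#' @rdname writeTable
#' @export
setMethod("writeTable", "data.frame", function(object, path, ...)
  .writeDF(object, path))

#' @rdname writeTable
#' @export
setMethod("writeTable", "DataFrame", function(object, path, ...)
  .writeDF(as.data.frame(object), path))

#' @rdname writeTable
#' @export
setMethod("writeTable", "MarkerSet", function(object, path, ...) {
  ml <- markerList(object)
  df <- data.frame(
    type = rep(names(ml), lengths(ml)),
    gene_id = unlist(ml, use.names = FALSE))
  if (!nrow(df)) df <- data.frame(type = character(0), gene_id = character(0))
  .writeDF(df, path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "ScExpr", function(object, path, ...) {
  x <- exprValues(object)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  # full precision for lossless numeric round-trips
  for (j in seq(2L, ncol(df))) df[[j]] <- sprintf("%.17g", df[[j]])
  .writeDF(df, path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "CellTypeCall", function(object, path, ...) {
  df <- callTable(object)
  hits <- hitCounts(object)
  colnames(hits) <- paste0("hits_", colnames(hits))
  .writeDF(cbind(df, hits[df$cell_id, , drop = FALSE]), path)
})

#' Read an expression matrix written by [writeTable()]
#'
#' @param path TSV path (first column `gene_id`, remaining columns cells).
#' @param transform transform tag to attach (see [ScExpr]).
#' @param floor_applied floor metadata to attach.
#' @return An [ScExpr] object.
#' @export
readExpressionMatrix <- function(path, transform, floor_applied = NA_real_) {
  raw <- .readTSV(path)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- as.character(raw[[1L]])
  ScExpr(m, transform = transform, floor_applied = floor_applied)
}

#' Read a YAML run configuration
#'
#' Convenience reader for a YAML file naming input paths and thresholds
#' (QC gates, marker-rule prevalences, DE floor, ...).  Returned as a
#' plain nested list; the caller passes the values on to the relevant
#' pipeline functions.
#'
#' @param path YAML file.
#' @return Nested list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stopc("scmge_missing_file", "file not found: %s", path)
  yaml::read_yaml(path)
}
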