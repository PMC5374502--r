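#' @include AllGenerics.R
NULL

.TRANSFORMS <- c("nRPKM", "norm_mRNA_mol", "log2p1", "vst", "zscore", "delta_ct")

setOldClass("hclust")

#' Raw gene-by-cell count matrix with annotation
#'
#' `ScCounts` holds a genes x cells matrix of non-negative integer counts
#' (sequencing read counts or molecule counts) together with a gene
#' annotation table (`rowData`: `gene_id`, `symbol`, `length_bp`,
#' `is_mitochondrial`) and a cell metadata table (`colData`: `cell_id`,
#' `condition`, `total_mapped_reads`, optional `group`).  It extends
#' [SummarizedExperiment::SummarizedExperiment] and is the sole raw input
#' of the pipeline.
#'
#' @slot unit either `"reads"` (read counts) or `"molecules"` (UMI-style
#'   molecule counts, required by [normMrnaMol()]).
#'
#' @param counts genes x cells matrix of non-negative integers (base or
#'   `Matrix` sparse matrix; coerced to dense).
#' @param genes `data.frame` with columns `gene_id` (unique), `symbol`,
#'   `length_bp` (>= 1) and `is_mitochondrial` (logical, not all `TRUE`).
#' @param cells `data.frame` with columns `cell_id` (unique), `condition`
#'   and `total_mapped_reads` (>= 0).
#' @param unit count unit, `"reads"` or `"molecules"`.
#' @return An `ScCounts` object.
#' @examples
#' genes <- data.frame(gene_id = c("g1", "g2"), symbol = c("A", "B"),
#'                     length_bp = c(1000L, 2000L),
#'                     is_mitochondrial = c(FALSE, TRUE))
#' cells <- data.frame(cell_id = c("c1", "c2"), condition = "E11.5",
#'                     total_mapped_reads = c(2e6, 3e6))
#' sc <- ScCounts(matrix(0:3, 2, dimnames = list(genes$gene_id, cells$cell_id)),
#'                genes, cells)
#' counts(sc)
#' @export
setClass("ScCounts",
  contains = "SummarizedExperiment",
  representation(unit = "character"))

setValidity("ScCounts", function(object) {
  msgs <- character(0)
  x <- SummarizedExperiment::assay(object, "counts")
  rd <- as.data.frame(SummarizedExperiment::rowData(object))
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  if (!object@unit %in% c("reads", "molecules"))
    msgs <- c(msgs, "unit must be 'reads' or 'molecules'")
  need_g <- c("gene_id", "symbol", "length_bp", "is_mitochondrial")
  if (!all(need_g %in% names(rd)))
    msgs <- c(msgs, paste("rowData must contain", paste(need_g, collapse = ", ")))
  else {
    if (anyDuplicated(rd$gene_id)) msgs <- c(msgs, "gene_id values must be unique")
    if (any(rd$length_bp < 1)) msgs <- c(msgs, "length_bp must be >= 1")
    if (all(rd$is_mitochondrial)) msgs <- c(msgs, "need at least one non-mitochondrial gene")
  }
  need_c <- c("cell_id", "condition", "total_mapped_reads")
  if (!all(need_c %in% names(cd)))
    msgs <- c(msgs, paste("colData must contain", paste(need_c, collapse = ", ")))
  else {
    if (anyDuplicated(cd$cell_id)) msgs <- c(msgs, "cell_id values must be unique")
    if (any(cd$total_mapped_reads < 0)) msgs <- c(msgs, "total_mapped_reads must be >= 0")
  }
  if (any(x < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (!.isWholeNumber(x)) msgs <- c(msgs, "counts must be integral")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ScCounts-class
#' @export
ScCounts <- function(counts, genes, cells, unit = c("reads", "molecules")) {
  unit <- match.arg(unit)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != nrow(genes))
    stopc("scmge_dim_mismatch", "count matrix has %d rows but gene table has %d",
          nrow(counts), nrow(genes))
  if (ncol(counts) != nrow(cells))
    stopc("scmge_dim_mismatch", "count matrix has %d columns but cell table has %d",
          ncol(counts), nrow(cells))
  dimnames(counts) <- list(as.character(genes$gene_id), as.character(cells$cell_id))
  if (!"group" %in% names(cells)) cells$group <- NA_character_
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$gene_id),
    colData = S4Vectors::DataFrame(cells, row.names = cells$cell_id))
  methods::new("ScCounts", se, unit = unit)
}

#' Normalized gene-by-cell expression matrix
#'
#' `ScExpr` holds a genes x cells matrix of real-valued expression
#' measurements tagged with the transform that produced it (one of
#' `nRPKM`, `norm_mRNA_mol`, `log2p1`, `vst`, `zscore`, `delta_ct`) and,
#' where a floor was imposed before the transform, the floor value.
#'
#' @slot transform character, the transform tag.
#' @slot floorApplied numeric, the floor applied on the log scale before
#'   the transform, or `NA` when no floor was used.
#'
#' @param values genes x cells numeric matrix.
#' @param genes `data.frame` with at least a unique `gene_id` column, or
#'   `NULL` to derive it from the matrix rownames.
#' @param cells `data.frame` with at least a unique `cell_id` column, or
#'   `NULL` to derive it from the matrix colnames.
#' @param transform transform tag, one of
#'   `r paste0('"', .TRANSFORMS, '"', collapse = ", ")`.
#' @param floor_applied floor used upstream of the transform (`NA` if none).
#' @return An `ScExpr` object.
#' @export
setClass("ScExpr",
  contains = "SummarizedExperiment",
  representation(transform = "character", floorApplied = "numeric"))

setValidity("ScExpr", function(object) {
  msgs <- character(0)
  x <- SummarizedExperiment::assay(object, "expr")
  rd <- as.data.frame(SummarizedExperiment::rowData(object))
  if (!length(object@transform) == 1L || !object@transform %in% .TRANSFORMS)
    msgs <- c(msgs, paste("transform must be one of:", paste(.TRANSFORMS, collapse = ", ")))
  if (!"gene_id" %in% names(rd) || anyDuplicated(rd$gene_id))
    msgs <- c(msgs, "rowData must contain unique gene_id")
  if (length(object@transform) == 1L &&
      object@transform %in% c("nRPKM", "norm_mRNA_mol") && any(x < 0))
    msgs <- c(msgs, sprintf("%s values must be >= 0", object@transform))
  if (length(object@transform) == 1L && object@transform == "zscore" && ncol(x) > 1L) {
    v <- .rowVars(x)
    bad <- v > 1e-16 & abs(rowMeans(x)) > 1e-8
    if (any(bad)) msgs <- c(msgs, "zscore rows with nonzero variance must have mean ~ 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname ScExpr-class
#' @export
ScExpr <- function(values, genes = NULL, cells = NULL, transform,
                   floor_applied = NA_real_) {
  values <- as.matrix(values)
  if (is.null(genes)) {
    if (is.null(rownames(values)))
      rownames(values) <- sprintf("G%04d", seq_len(nrow(values)))
    genes <- data.frame(gene_id = rownames(values))
  }
  if (is.null(cells)) {
    if (is.null(colnames(values)))
      colnames(values) <- sprintf("C%04d", seq_len(ncol(values)))
    cells <- data.frame(cell_id = colnames(values))
  }
  dimnames(values) <- list(as.character(genes$gene_id), as.character(cells$cell_id))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$gene_id),
    colData = S4Vectors::DataFrame(cells, row.names = cells$cell_id))
  methods::new("ScExpr", se, transform = transform, floorApplied = floor_applied)
}

#' Differential expression result table
#'
#' A [S4Vectors::DataFrame] subclass with one row per gene and columns
#' `gene_id`, `tested`, `p_value`, `p_adjusted`, `lfc`, `n_A`, `n_B`.
#' Untested genes (failing the count prefilter) carry `p_value = 1`,
#' `lfc = 0` and are excluded from the multiple-testing adjustment.
#' `metadata()` records the adjustment method, the log2 floor and the
#' group definitions.
#'
#' @export
setClass("DEResult", contains = "DFrame")

setValidity("DEResult", function(object) {
  need <- c("gene_id", "tested", "p_value", "p_adjusted", "lfc", "n_A", "n_B")
  msgs <- character(0)
  if (!all(need %in% colnames(object)))
    return(paste("DEResult needs columns:", paste(need, collapse = ", ")))
  if (any(object$p_value <= 0 | object$p_value > 1, na.rm = TRUE))
    msgs <- c(msgs, "p_value must lie in (0, 1]")
  if (any(!object$tested & (object$p_value != 1 | object$lfc != 0)))
    msgs <- c(msgs, "untested genes must have p_value = 1 and lfc = 0")
  if (length(msgs)) msgs else TRUE
})

DEResult <- function(df, metadata = list()) {
  out <- methods::new("DEResult", S4Vectors::DataFrame(df))
  S4Vectors::metadata(out) <- metadata
  out
}

#' Derived cell-type marker sets
#'
#' Maps each cell-type label to the gene ids that satisfy the prevalence
#' rule that produced them (see [deriveMarkers()] and [markerRule()]).
#'
#' @slot markers named list of character vectors of gene ids.
#' @slot rule the `MarkerRule` list the set was derived under.
#' @slot provenance free-text dataset identifier.
#' @export
setClass("MarkerSet",
  representation(markers = "list", rule = "list", provenance = "character"))

setValidity("MarkerSet", function(object) {
  if (is.null(names(object@markers)) && length(object@markers))
    return("markers must be a named list")
  TRUE
})

#' Per-cell rule-based type assignments
#'
#' @slot hits cells x types matrix of marker hit counts.
#' @slot assigned named character vector: a type label, `"unassigned"`,
#'   `"excluded_conflict"` or `"excluded_implausible"` per cell.
#' @slot minMarkers the hit threshold used for assignment.
#' @export
setClass("CellTypeCall",
  representation(hits = "matrix", assigned = "character", minMarkers = "integer"))

#' Principal component model
#'
#' Exact SVD-based PCA of gene-centered, variance-stabilized expression
#' restricted to the selected variable genes.
#'
#' @slot variableGenes ordered character vector of the genes used.
#' @slot scores cells x k score matrix.
#' @slot loadings genes x k orthonormal loading matrix.
#' @slot varianceExplained per-component fraction of total variance,
#'   non-increasing.
#' @slot center per-gene means removed before the SVD.
#' @export
setClass("PCModel",
  representation(variableGenes = "character", scores = "matrix",
                 loadings = "matrix", varianceExplained = "numeric",
                 center = "numeric"))

setValidity("PCModel", function(object) {
  msgs <- character(0)
  k <- ncol(object@loadings)
  if (k) {
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(k))) > 1e-8)
      msgs <- c(msgs, "loadings must be orthonormal")
  }
  ve <- object@varianceExplained
  if (length(ve) > 1L && any(diff(ve) > 1e-12))
    msgs <- c(msgs, "varianceExplained must be non-increasing")
  if (any(ve < -1e-12 | ve > 1 + 1e-12))
    msgs <- c(msgs, "varianceExplained must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Hierarchical clustering result
#'
#' @slot tree the agglomeration tree (an [stats::hclust] object).
#' @slot leafOrder item ids in dendrogram leaf order.
#' @slot labels named integer vector of flat cluster labels at the
#'   requested cut (length 0 when no `k` was given).
#' @slot axis which axis was clustered, `"cells"` or `"genes"`.
#' @export
setClass("ClusterResult",
  representation(tree = "hclust", leafOrder = "character",
                 labels = "integer", axis = "character"))

#' Single-cell qPCR Ct matrix
#'
#' Genes x cells matrix of qPCR cycle-threshold values with `NA` marking
#' missing (never-amplified) reactions.
#'
#' @slot ct numeric matrix, values in `(0, missingFill]` or `NA`.
#' @slot referenceGene housekeeping gene used for delta-Ct (default Actb).
#' @slot missingFill Ct value substituted for missing entries (default 40).
#'
#' @param ct genes x cells numeric matrix with rownames; `NA` = missing.
#' @param reference_gene reference gene id, must be a rowname of `ct`.
#' @param missing_fill fill value for missing Ct entries.
#' @return A `CtMatrix` object.
#' @export
setClass("CtMatrix",
  representation(ct = "matrix", referenceGene = "character",
                 missingFill = "numeric"))

setValidity("CtMatrix", function(object) {
  msgs <- character(0)
  if (is.null(rownames(object@ct)))
    return("ct matrix must have gene rownames")
  if (!object@referenceGene %in% rownames(object@ct))
    msgs <- c(msgs, sprintf("reference gene '%s' not present", object@referenceGene))
  v <- object@ct[!is.na(object@ct)]
  if (any(v <= 0 | v > object@missingFill))
    msgs <- c(msgs, "Ct values must lie in (0, missing_fill]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CtMatrix-class
#' @export
CtMatrix <- function(ct, reference_gene = "Actb", missing_fill = 40) {
  ct <- as.matrix(ct)
  if (is.null(colnames(ct))) colnames(ct) <- sprintf("C%04d", seq_len(ncol(ct)))
  if (!reference_gene %in% rownames(ct))
    stopc("scmge_missing_reference", "reference gene '%s' not in Ct matrix", reference_gene)
  methods::new("CtMatrix", ct = ct, referenceGene = reference_gene,
               missingFill = missing_fill)
}
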