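#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor functions for the package's S4 classes; prefer these
#' over direct slot access.
#'
#' @param object one of the package's S4 objects.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("counts", "ScCounts", function(object, ...)
  SummarizedExperiment::assay(object, "counts"))

#' @rdname accessors
#' @export
setMethod("countUnit", "ScCounts", function(object) object@unit)

#' @rdname accessors
#' @export
setMethod("exprValues", "ScExpr", function(object)
  SummarizedExperiment::assay(object, "expr"))

#' @rdname accessors
#' @export
setMethod("exprTransform", "ScExpr", function(object) object@transform)

#' @rdname accessors
#' @export
setMethod("floorApplied", "ScExpr", function(object) object@floorApplied)

#' @rdname accessors
#' @export
setMethod("geneData", "SummarizedExperiment", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)))

#' @rdname accessors
#' @export
setMethod("cellData", "SummarizedExperiment", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

#' @rdname accessors
#' @export
setMethod("markerList", "MarkerSet", function(object) object@markers)

#' @rdname accessors
#' @export
setMethod("markerRuleUsed", "MarkerSet", function(object) object@rule)

#' @rdname accessors
#' @export
setMethod("hitCounts", "CellTypeCall", function(object) object@hits)

#' @rdname accessors
#' @export
setMethod("callTable", "CellTypeCall", function(object)
  data.frame(cell_id = names(object@assigned), assigned = unname(object@assigned)))

#' @rdname accessors
#' @export
setMethod("pcScores", "PCModel", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("pcLoadings", "PCModel", function(object) object@loadings)

#' @rdname accessors
#' @export
setMethod("varianceExplained", "PCModel", function(object) object@varianceExplained)

#' @rdname accessors
#' @export
setMethod("variableGenes", "PCModel", function(object) object@variableGenes)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("clusterTree", "ClusterResult", function(object) object@tree)

#' @rdname accessors
#' @export
setMethod("leafOrder", "ClusterResult", function(object) object@leafOrder)

#' @rdname accessors
#' @export
setMethod("ctValues", "CtMatrix", function(object) object@ct)

#' @rdname accessors
#' @export
setMethod("referenceGene", "CtMatrix", function(object) object@referenceGene)

#' @rdname accessors
#' @export
setMethod("missingFill", "CtMatrix", function(object) object@missingFill)

setMethod("show", "ScCounts", function(object) {
  cat(sprintf("ScCounts: %d genes x %d cells [unit: %s]\n",
              nrow(object), ncol(object), object@unit))
  cat(sprintf("  conditions: %s\n",
              paste(unique(SummarizedExperiment::colData(object)$condition),
                    collapse = ", ")))
  cat(sprintf("  mitochondrial genes: %d\n",
              sum(SummarizedExperiment::rowData(object)$is_mitochondrial)))
})

setMethod("show", "ScExpr", function(object) {
  fl <- if (is.na(object@floorApplied)) "" else
    sprintf(", floor %g", object@floorApplied)
  cat(sprintf("ScExpr: %d genes x %d cells [transform: %s%s]\n",
              nrow(object), ncol(object), object@transform, fl))
})

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet (%s): %d types\n", object@provenance,
              length(object@markers)))
  for (ty in names(object@markers))
    cat(sprintf("  %s: %d markers\n", ty, length(object@markers[[ty]])))
})

setMethod("show", "CellTypeCall", function(object) {
  tab <- table(object@assigned)
  cat(sprintf("CellTypeCall: %d cells (min markers %d)\n",
              length(object@assigned), object@minMarkers))
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
})

setMethod("show", "PCModel", function(object) {
  cat(sprintf("PCModel: %d cells x %d components on %d genes\n",
              nrow(object@scores), ncol(object@scores),
              length(object@variableGenes)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(object@varianceExplained, 4)),
            collapse = " "), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d %s", length(object@leafOrder), object@axis))
  if (length(object@labels))
    cat(sprintf(", %d flat clusters", length(unique(object@labels))))
  cat("\n")
})

setMethod("show", "CtMatrix", function(object) {
  cat(sprintf("CtMatrix: %d genes x %d cells (ref %s, fill %g, %d missing)\n",
              nrow(object@ct), ncol(object@ct), object@referenceGene,
              object@missingFill, sum(is.na(object@ct))))
})
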