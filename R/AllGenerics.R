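#' @include utils.R
NULL

#' @export
setGeneric("countUnit", function(object) standardGeneric("countUnit"))

#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @export
setGeneric("exprTransform", function(object) standardGeneric("exprTransform"))

#' @export
setGeneric("floorApplied", function(object) standardGeneric("floorApplied"))

#' @export
setGeneric("geneData", function(object) standardGeneric("geneData"))

#' @export
setGeneric("cellData", function(object) standardGeneric("cellData"))

#' @export
setGeneric("markerList", function(object) standardGeneric("markerList"))

#' @export
setGeneric("markerRuleUsed", function(object) standardGeneric("markerRuleUsed"))

#' @export
setGeneric("callTable", function(object) standardGeneric("callTable"))

#' @export
setGeneric("hitCounts", function(object) standardGeneric("hitCounts"))

#' @export
setGeneric("pcScores", function(object) standardGeneric("pcScores"))

#' @export
setGeneric("pcLoadings", function(object) standardGeneric("pcLoadings"))

#' @export
setGeneric("varianceExplained", function(object) standardGeneric("varianceExplained"))

#' @export
setGeneric("variableGenes", function(object) standardGeneric("variableGenes"))

#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @export
setGeneric("clusterTree", function(object) standardGeneric("clusterTree"))

#' @export
setGeneric("leafOrder", function(object) standardGeneric("leafOrder"))

#' @export
setGeneric("ctValues", function(object) standardGeneric("ctValues"))

#' @export
setGeneric("referenceGene", function(object) standardGeneric("referenceGene"))

#' @export
setGeneric("missingFill", function(object) standardGeneric("missingFill"))

#' @export
setGeneric("writeTable", function(object, path, ...) standardGeneric("writeTable"))
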