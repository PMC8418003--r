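#' @rdname vertexNames
#' @export
setGeneric("vertexNames", function(x) standardGeneric("vertexNames"))

#' @rdname vertexWeights
#' @export
setGeneric("vertexWeights", function(x) standardGeneric("vertexWeights"))

#' @rdname edgeWeights
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname numEdges
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname numVertices
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' @rdname exprValues
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname sampleLabels
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname loocvFolds
#' @export
setGeneric("loocvFolds", function(x) standardGeneric("loocvFolds"))

#' @rdname rocPoints
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname aucValue
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname gridTable
#' @export
setGeneric("gridTable", function(x) standardGeneric("gridTable"))

#' @rdname bestParams
#' @export
setGeneric("bestParams", function(x) standardGeneric("bestParams"))
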