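#' @rdname TranscriptomeTruth-class
#' @param x A `TranscriptomeTruth` or `TxCounts` object.
#' @export
setGeneric("orthologMap", function(x) standardGeneric("orthologMap"))

#' @rdname TranscriptomeTruth-class
#' @export
setGeneric("aOnlySet", function(x) standardGeneric("aOnlySet"))

#' @rdname TranscriptomeTruth-class
#' @export
setGeneric("tissueAssignment", function(x) standardGeneric("tissueAssignment"))

#' @rdname TranscriptomeTruth-class
#' @export
setGeneric("expressionLevel", function(x) standardGeneric("expressionLevel"))

#' @rdname TxCounts-class
#' @export
setGeneric("coverageList", function(x) standardGeneric("coverageList"))

#' @rdname TxCounts-class
#' @export
setGeneric("avgCoverage", function(x) standardGeneric("avgCoverage"))

#' @rdname TxCounts-class
#' @export
setGeneric("txLengths", function(x) standardGeneric("txLengths"))

setMethod("orthologMap", "TranscriptomeTruth", function(x) x@orthologMap)
setMethod("aOnlySet", "TranscriptomeTruth", function(x) x@aOnlySet)
setMethod("tissueAssignment", "TranscriptomeTruth",
          function(x) x@tissueAssignment)
setMethod("expressionLevel", "TranscriptomeTruth",
          function(x) x@expressionLevel)

#' @rdname TxCounts-class
#' @aliases counts,TxCounts-method
#' @param object A `TxCounts` object.
#' @importMethodsFrom BiocGenerics counts
#' @exportMethod counts
setMethod("counts", "TxCounts", function(object) object@counts)

setMethod("coverageList", "TxCounts", function(x) x@coverage)
setMethod("txLengths", "TxCounts", function(x) x@txLengths)

#' @rdname TxCounts-class
#' @aliases avgCoverage,TxCounts-method
setMethod("avgCoverage", "TxCounts", function(x) {
  vapply(names(x@coverage),
         function(id) sum(x@coverage[[id]]) / x@txLengths[[id]],
         numeric(1))
})
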