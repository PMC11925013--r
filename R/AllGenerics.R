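#' @rdname networkSummary
#' @export
setGeneric("networkSummary", function(x, ...) standardGeneric("networkSummary"))

#' @rdname detectCommunities
#' @export
setGeneric("detectCommunities", function(x, seed = 1L, ...)
  standardGeneric("detectCommunities"))

#' @rdname assignWeights
#' @export
setGeneric("assignWeights", function(x, suspiciousPenalty = 2, ...)
  standardGeneric("assignWeights"))

#' @rdname minimumSpanningForest
#' @export
setGeneric("minimumSpanningForest", function(x, seed = 1L, ...)
  standardGeneric("minimumSpanningForest"))

#' @rdname cycleCensus
#' @export
setGeneric("cycleCensus", function(x, maxLen = 6L, ...)
  standardGeneric("cycleCensus"))

#' @rdname asIgraph
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' Accessors for duplication-network classes
#'
#' `regions()` returns the node `GRanges`; `alignments()` the parsed
#' alignment table; `edgeTable()` the (trimmed) edge table; `selfLoops()`
#' and `doubleEdges()` the per-node pre-trim counts; `nNodes()` the node
#' count; `duplicationCounts()` the per-node duplication counts of a
#' spanning forest (its node degrees); `forestEdges()` the forest edge
#' table.
#'
#' @param x an `SDNetwork`, `SimulatedNetwork` or `SpanningForest`.
#' @return See the individual accessor descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("selfLoops", function(x) standardGeneric("selfLoops"))

#' @rdname accessors
#' @export
setGeneric("doubleEdges", function(x) standardGeneric("doubleEdges"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("duplicationCounts", function(x) standardGeneric("duplicationCounts"))

#' @rdname accessors
#' @export
setGeneric("forestEdges", function(x) standardGeneric("forestEdges"))

#' @rdname accessors
#' @export
setGeneric("trueDuplicationCounts", function(x)
  standardGeneric("trueDuplicationCounts"))

#' @rdname accessors
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' @rdname accessors
#' @export
setGeneric("signatureWeights", function(x) standardGeneric("signatureWeights"))
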