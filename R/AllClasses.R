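#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width reduce findOverlaps pintersect
#' @importFrom IRanges IRanges
NULL

#' SDNetwork: a network of duplicated genomic regions
#'
#' Nodes are duplicated regions (maximal unions of overlapping alignment
#' intervals, one [GenomicRanges::GRanges] row each); edges connect two
#' regions whenever at least one pairwise alignment joins them.  The graph
#' is simple: parallel alignments between the same region pair are collapsed
#' into one edge carrying their multiplicity (`nAlignments`) and maximal
#' identity, and alignments internal to a single region are recorded as
#' per-node self-loop counts rather than edges.  The pre-trim multiplicity
#' and self-loop counts are retained because they are themselves features of
#' actively duplicating loci.
#'
#' @slot regions `GRanges`, one row per node, with a `node` integer id in
#'   `mcols`.
#' @slot alignments `data.frame` of the parsed pairwise alignments with the
#'   node each interval maps to (`nodeA`, `nodeB`), genomic coordinates of
#'   both intervals (0-based half-open, as in the input dialect) and the
#'   fraction identity.
#' @slot edges `data.frame` with one row per (trimmed) edge: `nodeA < nodeB`,
#'   `nAlignments`, `maxIdentity`, `intrachromosomal`, `suspicious`,
#'   `weight` (NA until [assignWeights()] is called).
#' @slot selfLoopCount integer, per node.
#' @slot doubleEdgeCount integer, per node: number of incident edges backed
#'   by more than one alignment.
#'
#' @seealso [buildNetwork()], [networkSummary()], [minimumSpanningForest()]
#' @export
setClass("SDNetwork",
  representation(
    regions = "GRanges",
    alignments = "data.frame",
    edges = "data.frame",
    selfLoopCount = "integer",
    doubleEdgeCount = "integer"
  )
)

setValidity("SDNetwork", function(object) {
  n <- length(object@regions)
  e <- object@edges
  msg <- character(0)
  need <- c("nodeA", "nodeB", "nAlignments", "maxIdentity",
            "intrachromosomal", "suspicious", "weight")
  if (!all(need %in% names(e)))
    msg <- c(msg, "edge table is missing required columns")
  if (nrow(e)) {
    if (any(e$nodeA == e$nodeB))
      msg <- c(msg, "self-loops are not allowed in the trimmed edge table")
    if (any(e$nodeA > e$nodeB))
      msg <- c(msg, "edges must be stored with nodeA < nodeB")
    if (anyDuplicated(paste(e$nodeA, e$nodeB)))
      msg <- c(msg, "parallel edges are not allowed in the trimmed edge table")
    if (any(e$nAlignments < 1L))
      msg <- c(msg, "every edge must be backed by at least one alignment")
    if (any(e$nodeB > n))
      msg <- c(msg, "edge endpoint beyond the node set")
  }
  if (length(object@selfLoopCount) != n || length(object@doubleEdgeCount) != n)
    msg <- c(msg, "per-node counts must have one entry per region")
  if (length(msg)) msg else TRUE
})

#' SimulatedNetwork: a preferential-copying-model grown network
#'
#' The outcome of [pcmSimulate()]: a simple undirected graph grown by
#' preferential copying, with per-edge sequence identity (a scalar molecular
#' clock), primary/secondary truth labels, gene-conversion hit flags, and
#' per-node true duplication counts.  Edges whose identity decayed below the
#' annotation floor (0.9) are retained in the table with `alive = FALSE` so
#' that the event bookkeeping stays complete.
#'
#' @slot nNodes integer.
#' @slot edges `data.frame`: `from`, `to`, `identity`, `isPrimary`,
#'   `nagcHit`, `alive`.
#' @slot trueDupCount integer per node: number of duplication events the
#'   node took part in.
#' @slot eventLog `data.frame`: `step`, `type` (`"duplication"`,
#'   `"innovation"`, `"nagc"`, `"loss"`), `actors`.
#' @slot params the [pcmParams()] list the simulation was run with.
#' @export
setClass("SimulatedNetwork",
  representation(
    nNodes = "integer",
    edges = "data.frame",
    trueDupCount = "integer",
    eventLog = "data.frame",
    params = "list"
  )
)

setValidity("SimulatedNetwork", function(object) {
  msg <- character(0)
  e <- object@edges
  if (length(object@trueDupCount) != object@nNodes)
    msg <- c(msg, "trueDupCount must have one entry per node")
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    live <- e$identity[e$alive]
    if (length(live) && (any(live < 0.9 - 1e-12) || any(live > 1 + 1e-12)))
      msg <- c(msg, "surviving edge identities must lie in [0.9, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' SpanningForest: reconstructed primary duplication events
#'
#' A per-component minimum spanning tree of a weighted duplication network:
#' an acyclic subgraph spanning every node, whose edges are the predicted
#' primary duplication events.  The per-node duplication count is the node
#' degree within the forest.
#'
#' @slot edges `data.frame`: `from`, `to`, `weight`.
#' @slot nNodes integer.
#' @slot nComponents integer, components of the *input* network (equals the
#'   number of trees in the forest).
#' @slot dupCount numeric per node: forest degree.
#' @export
setClass("SpanningForest",
  representation(
    edges = "data.frame",
    nNodes = "integer",
    nComponents = "integer",
    dupCount = "integer"
  )
)

setValidity("SpanningForest", function(object) {
  msg <- character(0)
  if (nrow(object@edges) != object@nNodes - object@nComponents)
    msg <- c(msg, "a spanning forest must have nNodes - nComponents edges")
  if (length(object@dupCount) != object@nNodes)
    msg <- c(msg, "dupCount must have one entry per node")
  if (nrow(object@edges) &&
      sum(object@dupCount) != 2L * nrow(object@edges))
    msg <- c(msg, "degree sum must equal twice the edge count")
  if (length(msg)) msg else TRUE
})

#' SignatureModel: a nonnegative factorization of windowed duplication features
#'
#' Holds the nonnegative input matrix `A` (genomic windows x features, after
#' mean-binning of selected features and column min-max scaling), the factor
#' pair `W` (windows x k) and `H` (k x features, the signatures), the KL loss
#' trace of the multiplicative updates, and the encoder (binning means and
#' column ranges) needed to place individual regions on the same scale.
#'
#' @slot A numeric matrix, windows x features, entries in [0, 1].
#' @slot W numeric matrix, windows x k, nonnegative.
#' @slot H numeric matrix, k x features, nonnegative.
#' @slot k integer rank.
#' @slot lossTrace numeric, KL divergence per recorded iteration
#'   (nonincreasing).
#' @slot encoder list: `binCols`, `binMeans`, `colMin`, `colMax`,
#'   `featureNames`.
#' @export
setClass("SignatureModel",
  representation(
    A = "matrix",
    W = "matrix",
    H = "matrix",
    k = "integer",
    lossTrace = "numeric",
    encoder = "list"
  )
)

setValidity("SignatureModel", function(object) {
  msg <- character(0)
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "W and H must be nonnegative")
  if (nrow(object@H) != object@k || ncol(object@W) != object@k)
    msg <- c(msg, "factor dimensions must match the rank k")
  if (ncol(object@A) != ncol(object@H) || nrow(object@A) != nrow(object@W))
    msg <- c(msg, "factor dimensions must match A")
  if (length(msg)) msg else TRUE
})
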