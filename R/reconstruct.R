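# Reconstruction of primary duplication events: shared-neighbor edge
# weights, Kruskal minimum spanning forest, per-node duplication counts,
# and permutation tests for forest enrichment/depletion.

# internal: adjacency list (neighbors only) from an edge list
.adjList <- function(from, to, n) {
  adj <- vector("list", n)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }
  adj
}

# internal: shared-neighbor weight for every edge of a simple graph:
# w = 1 - |N(a) \cap N(b)| / min(k_a, k_b); N(x) excludes x itself.
.sharedNeighborWeights <- function(from, to, n) {
  adj <- .adjList(from, to, n)
  deg <- lengths(adj)
  vapply(seq_along(from), function(i) {
    a <- from[i]; b <- to[i]
    shared <- sum(adj[[a]] %in% adj[[b]])
    1 - shared / min(deg[a], deg[b])
  }, numeric(1))
}

#' Shared-neighbor weight of one network edge
#'
#' The weight of an edge (a, b) is `1 - |N(a) n N(b)| / min(k_a, k_b)`:
#' the more neighbors its endpoints share, the lighter the edge, and the
#' more likely it represents a real (primary) duplication event, because a
#' daughter region inherits neighbors from its mother.  Weights lie in
#' (0, 1]; the weight is exactly 1 when no neighbors are shared, and is
#' always positive because `a` is never in `N(a)` nor `b` in `N(b)`.
#'
#' @param net an `SDNetwork` or `SimulatedNetwork`.
#' @param a,b node indices of an existing edge.
#' @return the weight, a number in (0, 1].
#' @export
edgeWeight <- function(net, a, b) {
  if (a == b) stop("an edge cannot join a node to itself")
  el <- .edgeEndpoints(net)
  hit <- which((el$from == a & el$to == b) | (el$from == b & el$to == a))
  if (!length(hit)) stop("edge (", a, ", ", b, ") is not in the network")
  .sharedNeighborWeights(el$from, el$to, el$n)[hit[1]]
}

# internal: uniform view of the live edge list of either network class
.edgeEndpoints <- function(net) {
  if (is(net, "SDNetwork")) {
    list(from = net@edges$nodeA, to = net@edges$nodeB, n = nNodes(net),
         suspicious = net@edges$suspicious)
  } else if (is(net, "SimulatedNetwork")) {
    e <- net@edges[net@edges$alive, , drop = FALSE]
    list(from = e$from, to = e$to, n = net@nNodes,
         suspicious = rep(FALSE, nrow(e)))
  } else stop("unsupported network class: ", class(net))
}

#' Assign reconstruction weights to all network edges
#'
#' Every non-suspicious edge receives its shared-neighbor weight (in
#' (0, 1]); suspicious edges (matching breakpoints away from assembly gaps,
#' see [flagSuspiciousEdges()]) receive `suspiciousPenalty` instead, which
#' exceeds every legitimate weight and therefore keeps them out of the
#' minimum spanning forest whenever a non-suspicious alternative exists.
#' If a component is connected only through suspicious edges, penalty edges
#' are still used (the forest must span) and a warning is emitted.
#'
#' @param x an `SDNetwork`.
#' @param suspiciousPenalty weight assigned to suspicious edges (> 1).
#' @param ... unused.
#' @return the network with its edges' `weight` column filled.
#' @rdname assignWeights
#' @export
setMethod("assignWeights", "SDNetwork", function(x, suspiciousPenalty = 2, ...) {
  if (suspiciousPenalty <= 1)
    stop("suspiciousPenalty must exceed 1 to dominate normal weights")
  e <- x@edges
  if (nrow(e) == 0) return(x)
  w <- .sharedNeighborWeights(e$nodeA, e$nodeB, nNodes(x))
  w[e$suspicious] <- suspiciousPenalty
  x@edges$weight <- w
  x
})

# internal: Kruskal with union-find; ties broken by a seeded random
# permutation, stable under (weight) sort.  Returns indices of selected
# edges.
.kruskal <- function(from, to, weight, n, seed) {
  m <- length(from)
  if (m == 0L) return(integer(0))
  set.seed(seed)
  ord <- sample.int(m)          # seeded tie-break
  ord <- ord[order(weight[ord])]  # stable sort by weight
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  picked <- integer(0)
  for (i in ord) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) {
      parent[ra] <- rb
      picked <- c(picked, i)
      if (length(picked) == n - 1L) break
    }
  }
  sort(picked)
}

.forestFromEdges <- function(from, to, weight, n, seed, suspicious = NULL) {
  idx <- .kruskal(from, to, weight, n, seed)
  if (!is.null(suspicious) && any(suspicious[idx]))
    warning(sum(suspicious[idx]), " suspicious edge(s) were required to ",
            "span their component")
  nComp <- n - length(idx)
  deg <- tabulate(c(from[idx], to[idx]), n)
  new("SpanningForest",
      edges = data.frame(from = from[idx], to = to[idx],
                         weight = weight[idx]),
      nNodes = as.integer(n),
      nComponents = as.integer(nComp),
      dupCount = as.integer(deg))
}

#' Minimum spanning forest of putative primary duplications
#'
#' Runs Kruskal's algorithm per connected component on the weighted
#' network, producing the acyclic spanning subgraph of minimal total weight
#' — the predicted set of primary duplication events.  The forest always
#' has `n_nodes - n_components` edges.  Ties between equal-weight edges are
#' broken by a seeded random order, so results are reproducible.
#'
#' For an `SDNetwork`, weights must have been assigned
#' ([assignWeights()]); for a `SimulatedNetwork`, shared-neighbor weights
#' are computed on the fly from the surviving graph.
#'
#' @param x an `SDNetwork` or `SimulatedNetwork`.
#' @param seed integer tie-break seed.
#' @param ... unused.
#' @return a [SpanningForest-class].
#' @rdname minimumSpanningForest
#' @export
setMethod("minimumSpanningForest", "SDNetwork", function(x, seed = 1L, ...) {
  e <- x@edges
  if (nrow(e) && anyNA(e$weight))
    stop("assign weights before building the forest (see assignWeights)")
  .forestFromEdges(e$nodeA, e$nodeB, e$weight, nNodes(x), seed,
                   suspicious = e$suspicious)
})

#' @rdname accessors
#' @export
setMethod("forestEdges", "SpanningForest", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("nNodes", "SpanningForest", function(x) x@nNodes)

#' Per-node duplication counts from a spanning forest
#'
#' The number of duplication events a node took part in is its degree
#' within the forest of primary events.  (Assigning event directionality
#' would require knowing each component's ancestral node; the degree is
#' invariant to that choice except at the starting nodes.)
#'
#' @param x a `SpanningForest`.
#' @return integer vector, one count per node.
#' @rdname accessors
#' @export
setMethod("duplicationCounts", "SpanningForest", function(x) x@dupCount)

setMethod("show", "SpanningForest", function(object) {
  cat("SpanningForest:", nrow(object@edges), "edges over", object@nNodes,
      "nodes in", object@nComponents, "trees\n")
  cat("  total weight:", sum(object@edges$weight),
      "| max node duplication count:", max(object@dupCount), "\n")
})

#' Permutation test for enrichment of an edge property in the forest
#'
#' Tests whether forest edges are enriched ("greater") or depleted
#' ("less") in some property (e.g. sequence identity above 0.99, or the
#' suspicious-breakpoint flag) relative to the rest of the network.  Each
#' of `nRounds` rounds draws `|forest|` edges uniformly without replacement
#' from the non-forest edges and counts how many satisfy the predicate; the
#' empirical p-value is `(1 + #{rounds at least as extreme}) / (nRounds +
#' 1)` (add-one convention, so p is never exactly zero).
#'
#' @param net an `SDNetwork` or `SimulatedNetwork`.
#' @param forest a `SpanningForest` over the same nodes.
#' @param edgePredicate function mapping the network's edge table (rows:
#'   edges) to a logical vector.
#' @param direction `"greater"` (enrichment) or `"less"` (depletion).
#' @param nRounds number of sampling rounds (default 10000).
#' @param seed integer seed.
#' @return list: `observed` (count among forest edges), `background`
#'   (vector of sampled counts), `p`.
#' @export
mstEnrichmentTest <- function(net, forest, edgePredicate,
                              direction = c("greater", "less"),
                              nRounds = 10000, seed = 1L) {
  direction <- match.arg(direction)
  if (nRounds < 1) stop("nRounds must be at least 1")
  e <- if (is(net, "SDNetwork")) net@edges else
    net@edges[net@edges$alive, , drop = FALSE]
  ends <- .edgeEndpoints(net)
  flag <- as.logical(edgePredicate(e))
  if (length(flag) != nrow(e))
    stop("edgePredicate must return one logical per edge")
  fkey <- paste(pmin(forest@edges$from, forest@edges$to),
                pmax(forest@edges$from, forest@edges$to))
  ekey <- paste(pmin(ends$from, ends$to), pmax(ends$from, ends$to))
  inForest <- ekey %in% fkey
  if (sum(inForest) != nrow(forest@edges))
    stop("forest edges must be a subset of the network's edges")
  k <- sum(inForest)
  pool <- which(!inForest)
  if (length(pool) < k)
    stop("fewer non-forest edges (", length(pool),
         ") than forest edges (", k, ")")
  observed <- sum(flag[inForest])
  set.seed(seed)
  background <- vapply(seq_len(nRounds), function(i)
    sum(flag[sample(pool, k)]), numeric(1))
  extreme <- if (direction == "greater") sum(background >= observed)
             else sum(background <= observed)
  list(observed = observed, background = background,
       p = (1 + extreme) / (nRounds + 1))
}
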