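#' Build duplicated regions from pairwise alignments
#'
#' A duplicated region is the union of all transitively overlapping
#' alignment intervals on a chromosome: each alignment contributes its two
#' intervals, and intervals overlapping by at least 1 bp are merged.
#' Bookended (touching but non-overlapping) intervals are kept separate.
#'
#' @param records alignment table from [parseSdAnnotation()].
#' @return a `GRanges`, one row per region, sorted by (chrom, start), with
#'   `mcols` columns `node` (integer id) and `members` (a `CharacterList`
#'   of contributing alignment ids, suffixed `:A`/`:B` by side).
#' @examples
#' rec <- data.frame(id = c("A1", "A2"),
#'   chromA = "chr1", startA = c(100, 1500), endA = c(2000, 3000),
#'   chromB = "chr2", startB = c(0, 5000), endB = c(1200, 6500),
#'   identity = 0.95)
#' buildDuplicatedRegions(rec)  # chr1 intervals merge into [100, 3000)
#' @export
buildDuplicatedRegions <- function(records) {
  if (nrow(records) == 0)
    return(GRanges())
  iv <- .alignmentIntervals(records)
  red <- reduce(iv, min.gapwidth = 0L, with.revmap = TRUE)
  red <- GenomicRanges::sort(red)
  members <- lapply(mcols(red)$revmap, function(i)
    paste0(records$id[mcols(iv)$rec[i]], ":", mcols(iv)$side[i]))
  out <- GRanges(seqnames(red), IRanges(start(red), end(red)))
  mcols(out)$node <- seq_along(out)
  mcols(out)$members <- IRanges::CharacterList(members)
  out
}

#' Build the segmental-duplication network
#'
#' Nodes are the duplicated regions; an edge joins two regions whenever an
#' alignment exists between them.  Alignments whose two intervals fall in
#' the same region become self-loop counts on that node (no edge); parallel
#' alignments between the same region pair collapse to a single edge whose
#' `nAlignments` records the multiplicity and `maxIdentity` their maximum.
#' Nodes incident to a multi-alignment edge get their `doubleEdges` count
#' incremented once per such edge.
#'
#' @param regions `GRanges` from [buildDuplicatedRegions()].
#' @param records the alignment table the regions were built from.
#' @return an [SDNetwork-class] object.
#' @export
buildNetwork <- function(regions, records) {
  n <- length(regions)
  iv <- .alignmentIntervals(records)
  ov <- findOverlaps(iv, regions)
  if (length(ov) != length(iv))
    stop("internal consistency error: ", length(iv) - length(S4Vectors::from(ov)),
         " alignment interval(s) not contained in any region")
  hit <- integer(length(iv))
  hit[S4Vectors::from(ov)] <- S4Vectors::to(ov)
  if (any(hit == 0L))
    stop("internal consistency error: alignment interval without a region")
  m <- nrow(records)
  nodeA <- hit[seq_len(m)]
  nodeB <- hit[m + seq_len(m)]
  aln <- cbind(records,
               nodeA = nodeA, nodeB = nodeB,
               stringsAsFactors = FALSE)

  selfLoop <- integer(n)
  isLoop <- nodeA == nodeB
  if (any(isLoop)) {
    t <- table(nodeA[isLoop])
    selfLoop[as.integer(names(t))] <- as.integer(t)
  }

  ea <- pmin(nodeA[!isLoop], nodeB[!isLoop])
  eb <- pmax(nodeA[!isLoop], nodeB[!isLoop])
  ident <- records$identity[!isLoop]
  if (length(ea)) {
    key <- paste(ea, eb)
    agg <- split(seq_along(key), key)
    first <- vapply(agg, `[`, integer(1), 1L)
    edges <- data.frame(
      nodeA = ea[first],
      nodeB = eb[first],
      nAlignments = vapply(agg, length, integer(1)),
      maxIdentity = vapply(agg, function(i) max(ident[i]), numeric(1)),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$nodeA, edges$nodeB), , drop = FALSE]
    rownames(edges) <- NULL
    edges$intrachromosomal <-
      as.character(seqnames(regions))[edges$nodeA] ==
      as.character(seqnames(regions))[edges$nodeB]
  } else {
    edges <- data.frame(nodeA = integer(0), nodeB = integer(0),
                        nAlignments = integer(0), maxIdentity = numeric(0),
                        intrachromosomal = logical(0))
  }
  edges$suspicious <- rep(FALSE, nrow(edges))
  edges$weight <- rep(NA_real_, nrow(edges))

  dbl <- integer(n)
  multi <- edges[edges$nAlignments > 1L, , drop = FALSE]
  if (nrow(multi)) {
    t <- table(c(multi$nodeA, multi$nodeB))
    dbl[as.integer(names(t))] <- as.integer(t)
  }

  new("SDNetwork", regions = regions, alignments = aln, edges = edges,
      selfLoopCount = selfLoop, doubleEdgeCount = dbl)
}

#' @rdname accessors
#' @export
setMethod("regions", "SDNetwork", function(x) x@regions)

#' @rdname accessors
#' @export
setMethod("alignments", "SDNetwork", function(x) x@alignments)

#' @rdname accessors
#' @export
setMethod("edgeTable", "SDNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("selfLoops", "SDNetwork", function(x) x@selfLoopCount)

#' @rdname accessors
#' @export
setMethod("doubleEdges", "SDNetwork", function(x) x@doubleEdgeCount)

#' @rdname accessors
#' @export
setMethod("nNodes", "SDNetwork", function(x) length(x@regions))

#' Convert a duplication network to an igraph graph
#'
#' @param x an `SDNetwork` or `SimulatedNetwork`.
#' @param ... unused.
#' @return an undirected simple [igraph::igraph] graph whose vertex ids are
#'   the node indices (for `SimulatedNetwork`, only surviving edges are
#'   included).
#' @rdname asIgraph
#' @export
setMethod("asIgraph", "SDNetwork", function(x, ...) {
  igraph::graph_from_data_frame(
    d = x@edges[, c("nodeA", "nodeB")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(nNodes(x)))
  )
})

setMethod("show", "SDNetwork", function(object) {
  s <- networkSummary(object)
  cat("SDNetwork with", s$n_nodes, "nodes,", s$n_edges, "edges,",
      s$n_components, "components\n")
  cat("  giant component:", s$giant_nodes, "nodes (",
      s$giant_node_share, "%), ", s$giant_edges, " edges (",
      s$giant_edge_share, "%)\n", sep = "")
  cat("  self-loops trimmed:", sum(object@selfLoopCount),
      "| multi-alignment edges:", sum(object@edges$nAlignments > 1L),
      "| suspicious edges:", sum(object@edges$suspicious), "\n")
})

# internal: component membership for a plain edge list over n nodes
.components <- function(from, to, n) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = from, to = to), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::components(g)$membership
}

.summaryFromEdges <- function(from, to, n) {
  if (n == 0L)
    return(list(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                giant_nodes = 0L, giant_edges = 0L,
                giant_node_share = 0, giant_edge_share = 0))
  memb <- .components(from, to, n)
  nc <- max(memb)
  sizes <- tabulate(memb, nc)
  giant <- which.max(sizes)
  gNodes <- sizes[giant]
  gEdges <- if (length(from)) sum(memb[from] == giant) else 0L
  list(
    n_nodes = n,
    n_edges = length(from),
    n_components = nc,
    giant_nodes = as.integer(gNodes),
    giant_edges = as.integer(gEdges),
    giant_node_share = round(100 * gNodes / n, 1),
    giant_edge_share = if (length(from))
      round(100 * gEdges / length(from), 1) else 0
  )
}

#' Summarize a duplication network
#'
#' Reports node/edge/component counts and the size of the giant (largest)
#' connected component, with node and edge shares as percentages rounded to
#' one decimal.  `n_nodes - n_components` is the number of edges any
#' spanning forest of the network must have.
#'
#' @param x an `SDNetwork` or `SimulatedNetwork`.
#' @param ... unused.
#' @return a list: `n_nodes`, `n_edges`, `n_components`, `giant_nodes`,
#'   `giant_edges`, `giant_node_share`, `giant_edge_share`.
#' @rdname networkSummary
#' @export
setMethod("networkSummary", "SDNetwork", function(x, ...) {
  .summaryFromEdges(x@edges$nodeA, x@edges$nodeB, nNodes(x))
})

#' Label-propagation communities
#'
#' Detects communities with the label propagation algorithm (each node
#' iteratively adopts the label most frequent among its neighbors, in
#' random order, until a fixed point).  Labels are arbitrary; the partition
#' is deterministic given `seed`.
#'
#' @param x an `SDNetwork` or `SimulatedNetwork`.
#' @param seed integer seed for the node update order and tie-breaks.
#' @param ... unused.
#' @return integer vector of community labels, one per node.
#' @rdname detectCommunities
#' @export
setMethod("detectCommunities", "SDNetwork", function(x, seed = 1L, ...) {
  .labelPropagation(asIgraph(x), seed)
})

.labelPropagation <- function(g, seed) {
  set.seed(seed)
  memb <- igraph::membership(igraph::cluster_label_prop(g))
  as.integer(memb)
}

#' Assign intervals to network nodes by longest overlap
#'
#' Each query interval is assigned to the duplicated region it overlaps the
#' most (by bp).  Exact ties go to the region lowest in (chrom, start)
#' order and are reported in the `tie` column; intervals overlapping no
#' region are unassigned (`NA`).
#'
#' @param net an `SDNetwork`.
#' @param intervals a `GRanges` of query intervals.
#' @return `data.frame` with one row per query: `node` (integer or `NA`),
#'   `overlap` (bp), `tie` (logical).
#' @export
mapIntervalsToNodes <- function(net, intervals) {
  reg <- regions(net)
  ov <- findOverlaps(intervals, reg)
  w <- width(suppressWarnings(pintersect(intervals[S4Vectors::from(ov)],
                                         reg[S4Vectors::to(ov)])))
  node <- rep(NA_integer_, length(intervals))
  best <- rep(NA_integer_, length(intervals))
  tie <- rep(FALSE, length(intervals))
  if (length(ov)) {
    for (q in unique(S4Vectors::from(ov))) {
      i <- which(S4Vectors::from(ov) == q)
      mx <- max(w[i])
      cand <- S4Vectors::to(ov)[i][w[i] == mx]
      # regions are sorted by (chrom, start), so min index is the tie-break
      node[q] <- min(cand)
      best[q] <- mx
      tie[q] <- length(cand) > 1L
    }
  }
  data.frame(node = node, overlap = best, tie = tie)
}

#' Flag suspicious (likely secondary) edges by matching breakpoints
#'
#' Two independent alignments at the same node that share a breakpoint
#' coordinate are the hallmark of a secondary alignment: a duplication that
#' overlapped an existing duplicated locus produces alignments cut at the
#' same position.  Every edge whose alignment shares a breakpoint (within
#' `tolBp`) with an alignment of a *different* edge incident to the same
#' node is flagged, unless the shared breakpoint lies within `gapPadBp` of
#' an assembly gap (matching breakpoints at gaps are an artifact of
#' assembly incompleteness, not of overlap).
#'
#' @param net an `SDNetwork`.
#' @param gaps `GRanges` of assembly gaps (possibly empty).
#' @param tolBp breakpoint matching tolerance in bp (default 0: exact).
#' @param gapPadBp distance to a gap within which a matching breakpoint is
#'   excused (default 50, the flank width used throughout).
#' @return the network with its edges' `suspicious` flag set.
#' @export
flagSuspiciousEdges <- function(net, gaps = GRanges(), tolBp = 0,
                                gapPadBp = 50) {
  aln <- alignments(net)
  edges <- edgeTable(net)
  if (nrow(edges) == 0) return(net)
  key <- paste(pmin(aln$nodeA, aln$nodeB), pmax(aln$nodeA, aln$nodeB))
  ekey <- paste(edges$nodeA, edges$nodeB)
  edgeOf <- match(key, ekey)   # NA for self-loop alignments

  nearGap <- function(chrom, pos) {
    if (length(gaps) == 0) return(rep(FALSE, length(pos)))
    q <- GRanges(chrom, IRanges(pmax(pos - gapPadBp, 0) + 1, pos + gapPadBp))
    IRanges::overlapsAny(q, gaps)
  }

  # per alignment side: node, breakpoint coords (0-based), chrom
  side <- data.frame(
    node = c(aln$nodeA, aln$nodeB),
    chrom = c(aln$chromA, aln$chromB),
    bp1 = c(aln$startA, aln$startB),
    bp2 = c(aln$endA, aln$endB),
    edge = rep(edgeOf, 2L),
    stringsAsFactors = FALSE
  )
  side <- side[!is.na(side$edge), , drop = FALSE]

  suspicious <- rep(FALSE, nrow(edges))
  for (nd in unique(side$node)) {
    s <- side[side$node == nd, , drop = FALSE]
    if (length(unique(s$edge)) < 2L) next
    bps <- data.frame(chrom = rep(s$chrom, 2L),
                      pos = c(s$bp1, s$bp2),
                      edge = rep(s$edge, 2L))
    for (i in seq_len(nrow(bps))) {
      close <- bps$chrom == bps$chrom[i] &
        abs(bps$pos - bps$pos[i]) <= tolBp &
        bps$edge != bps$edge[i]
      if (any(close)) {
        if (!nearGap(bps$chrom[i], bps$pos[i])) {
          suspicious[bps$edge[i]] <- TRUE
          suspicious[bps$edge[close]] <- TRUE
        }
      }
    }
  }
  net@edges$suspicious <- suspicious
  net
}

#' Census of chordless cycles and shortest self-paths
#'
#' Counts chordless cycles (cycles with no shortcut edge between
#' non-consecutive members) of length 3 up to `maxLen`, and computes per
#' node the length of the shortest cycle passing through it (`Inf` when the
#' node lies on no cycle).  Enumeration is exponential in `maxLen`, which
#' is therefore capped at 8.
#'
#' @param x an `SDNetwork` or `SimulatedNetwork`.
#' @param maxLen maximal cycle length to count, in [3, 8].
#' @param ... unused.
#' @return list with `cycles` (named integer vector, counts per length
#'   3..maxLen) and `shortestSelfPath` (numeric per node).
#' @rdname cycleCensus
#' @export
setMethod("cycleCensus", "SDNetwork", function(x, maxLen = 6L, ...) {
  .cycleCensus(edgeTable(x)$nodeA, edgeTable(x)$nodeB, nNodes(x), maxLen)
})

.cycleCensus <- function(from, to, n, maxLen) {
  maxLen <- as.integer(maxLen)
  if (maxLen < 3L) stop("maxLen must be at least 3")
  if (maxLen > 8L) stop("maxLen above 8 is not supported (exponential)")
  adj <- vector("list", n)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }
  hasEdge <- new.env(hash = TRUE, size = max(1L, 2L * length(from)))
  for (i in seq_along(from)) {
    assign(paste(from[i], to[i]), TRUE, envir = hasEdge)
    assign(paste(to[i], from[i]), TRUE, envir = hasEdge)
  }
  connected <- function(a, b) exists(paste(a, b), envir = hasEdge)

  counts <- integer(maxLen - 2L)
  names(counts) <- as.character(3:maxLen)

  # enumerate chordless cycles with canonical root = smallest member;
  # path grows only through vertices > root, second vertex < last vertex
  # at closure to count each cycle once
  for (root in seq_len(n)) {
    nb <- adj[[root]]
    nb <- nb[nb > root]
    if (length(nb) < 2L) next
    paths <- list()
    for (v in nb) paths[[length(paths) + 1L]] <- v
    len <- 1L
    while (len < maxLen - 1L && length(paths)) {
      nxt <- list()
      for (p in paths) {
        last <- p[length(p)]
        for (w in adj[[last]]) {
          if (w <= root || w %in% p) next
          # chordless: w may connect only to `last` among path members
          # (closure back to root checked separately)
          inner <- p[-length(p)]
          if (length(inner) && any(vapply(inner, connected, logical(1),
                                          b = w))) next
          cand <- c(p, w)
          # closes a cycle?
          if (connected(w, root) && length(cand) >= 3L) {
            # root's two cycle-neighbors are cand[1] and w; chordless also
            # requires no chord from root into the interior
            interior <- cand[-c(1L, length(cand))]
            if (!(length(interior) &&
                  any(vapply(interior, connected, logical(1), b = root)))) {
              if (cand[1] < w)  # canonical orientation
                counts[as.character(length(cand) + 1L)] <-
                  counts[as.character(length(cand) + 1L)] + 1L
            }
          }
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
      paths <- nxt
      len <- len + 1L
    }
    # triangles: pairs of root-neighbors that are connected
    for (i in seq_along(nb)) for (j in seq_len(i - 1L))
      if (connected(nb[i], nb[j]))
        counts["3"] <- counts["3"] + 1L
  }

  # shortest cycle through each node: for node v and each incident edge
  # (v,u), shortest path v..u avoiding that edge, plus 1
  ssp <- rep(Inf, n)
  if (length(from)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    for (v in seq_len(n)) {
      if (length(adj[[v]]) < 2L) next
      best <- Inf
      for (u in adj[[v]]) {
        eid <- igraph::get_edge_ids(g, c(v, u))
        g2 <- igraph::delete_edges(g, eid)
        d <- igraph::distances(g2, v = v, to = u)[1, 1]
        if (is.finite(d)) best <- min(best, d + 1)
      }
      ssp[v] <- best
    }
  }
  list(cycles = counts, shortestSelfPath = ssp)
}
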