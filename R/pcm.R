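# Preferential copying model (PCM) simulator with two molecular-evolution
# extensions: clock-like sequence-identity decay with edge loss below the
# 90% annotation floor, and non-allelic gene conversion (NAGC) resetting
# edge identities with donor-to-acceptor copying across shared neighbors.
#
# The simulation state is an environment holding flat edge arrays (grown by
# doubling) plus per-node adjacency (edge-index lists), so each step is a
# handful of vectorized operations.

#' Parameters of a PCM simulation
#'
#' @param nFinal target number of nodes.
#' @param f probability that the daughter inherits each edge of its mother
#'   (secondary-edge creation); `f = 0` grows a forest of primary edges
#'   only.
#' @param pNew probability that a step seeds a fresh two-node component
#'   (an innovation) instead of duplicating an existing node.
#' @param alpha preferential-choice offset: the mother is chosen with
#'   probability proportional to `degree + alpha`.  `alpha = 1` keeps
#'   degree-0 remnants (possible after edge loss) selectable.
#' @param delta identity decrement applied to every edge per step.  When
#'   `NULL`, derived from `rdRmRatio`: with the per-base duplication rate
#'   `r_d` comparable to the mutation rate `r_m` (`r_d/r_m = 1`), surviving
#'   copies diverge by about 5% over the run, i.e. `delta =
#'   0.1 / (rdRmRatio * T)` with `T` the expected number of growth steps.
#' @param rdRmRatio ratio of duplication to mutation rate, in [1, 2];
#'   only used when `delta` is `NULL`.
#' @param rGc per-edge per-step probability of a gene-conversion event
#'   (identity reset to 1).  See [calibrateRgc()] for tuning this to an
#'   end-of-run affected fraction.
#' @param nagcEvasion when `TRUE` (default), edges whose identity fell
#'   below 0.9 (and were therefore removed) evade gene conversion; when
#'   `FALSE`, conversion can also resurrect removed edges.
#' @param identityFloor edges below this identity are removed (0.9, the
#'   segmental-duplication annotation threshold).
#' @param stepOrder order of the three within-step processes.
#' @return a named list of class `pcmParams`.
#' @export
pcmParams <- function(nFinal = 6600, f = 0.35, pNew = 0.43, alpha = 1,
                      delta = NULL, rdRmRatio = 1.5, rGc = 0,
                      nagcEvasion = TRUE, identityFloor = 0.9,
                      stepOrder = c("growth", "nagc", "decay")) {
  stopifnot(nFinal >= 2, f >= 0, f <= 1, pNew >= 0, pNew <= 1,
            alpha >= 0, rGc >= 0, rGc <= 1)
  if (is.null(delta)) {
    tExp <- nFinal / (1 + pNew)
    delta <- (1 - identityFloor) / (rdRmRatio * tExp)
  }
  stopifnot(delta >= 0)
  structure(list(nFinal = as.integer(nFinal), f = f, pNew = pNew,
                 alpha = alpha, delta = delta, rdRmRatio = rdRmRatio,
                 rGc = rGc, nagcEvasion = nagcEvasion,
                 identityFloor = identityFloor,
                 stepOrder = match.arg(stepOrder, several.ok = TRUE)),
            class = "pcmParams")
}

#' Create a fresh simulation state
#'
#' The initial state is a single ancestral pair: two nodes joined by a
#' primary edge at identity 1, each credited with one duplication.
#'
#' @return an environment usable with [pcmStep()], [applyDecay()],
#'   [applyNagc()].
#' @export
newPcmState <- function() {
  st <- new.env(parent = emptyenv())
  cap <- 1024L
  st$n <- 2L
  st$deg <- c(1L, 1L, integer(cap - 2L))
  st$trueDup <- c(1L, 1L, integer(cap - 2L))
  st$adj <- c(list(1L, 1L), vector("list", cap - 2L))
  st$m <- 1L
  ecap <- 2048L
  st$eFrom <- c(1L, integer(ecap - 1L))
  st$eTo <- c(2L, integer(ecap - 1L))
  st$eId <- c(1, numeric(ecap - 1L))
  st$ePrimary <- c(TRUE, logical(ecap - 1L))
  st$eNagc <- logical(ecap)
  st$eAlive <- c(TRUE, logical(ecap - 1L))
  st$step <- 0L
  st$logStep <- integer(0)
  st$logType <- character(0)
  st$logActors <- character(0)
  st$nEvents <- 1L   # the ancestral duplication
  st
}

.growNodes <- function(st, k) {
  while (st$n + k > length(st$deg)) {
    extra <- length(st$deg)
    st$deg <- c(st$deg, integer(extra))
    st$trueDup <- c(st$trueDup, integer(extra))
    st$adj <- c(st$adj, vector("list", extra))
  }
}

.growEdges <- function(st, k) {
  while (st$m + k > length(st$eFrom)) {
    extra <- length(st$eFrom)
    st$eFrom <- c(st$eFrom, integer(extra))
    st$eTo <- c(st$eTo, integer(extra))
    st$eId <- c(st$eId, numeric(extra))
    st$ePrimary <- c(st$ePrimary, logical(extra))
    st$eNagc <- c(st$eNagc, logical(extra))
    st$eAlive <- c(st$eAlive, logical(extra))
  }
}

.addEdge <- function(st, a, b, identity, primary) {
  .growEdges(st, 1L)
  st$m <- st$m + 1L
  i <- st$m
  st$eFrom[i] <- a; st$eTo[i] <- b
  st$eId[i] <- identity
  st$ePrimary[i] <- primary
  st$eNagc[i] <- FALSE
  st$eAlive[i] <- TRUE
  st$adj[[a]] <- c(st$adj[[a]], i)
  st$adj[[b]] <- c(st$adj[[b]], i)
  st$deg[a] <- st$deg[a] + 1L
  st$deg[b] <- st$deg[b] + 1L
  i
}

.logEvent <- function(st, type, actors) {
  k <- length(st$logStep) + 1L
  st$logStep[k] <- st$step
  st$logType[k] <- type
  st$logActors[k] <- actors
}

# alive incident edges of node v
.aliveInc <- function(st, v) {
  ids <- st$adj[[v]]
  ids[st$eAlive[ids]]
}

# alive neighbors of v, with the edge index to each
.neighbors <- function(st, v) {
  ids <- .aliveInc(st, v)
  other <- st$eFrom[ids] + st$eTo[ids] - v
  list(nodes = other, edges = ids)
}

#' One growth step of the preferential copying model
#'
#' With probability `pNew` a fresh two-node component is seeded (primary
#' edge at identity 1).  Otherwise a mother node is chosen with probability
#' proportional to `degree + alpha`, a daughter node is added with a
#' primary mother-daughter edge at identity 1, and each neighbor of the
#' mother is independently inherited with probability `f`: the secondary
#' daughter-neighbor edge copies the *current* mother-neighbor identity.
#' Both mother and daughter are credited with one duplication.
#'
#' @param st state environment from [newPcmState()].
#' @param params a [pcmParams()] list.
#' @return the state, invisibly (modified in place).
#' @export
pcmStep <- function(st, params) {
  if (st$n < 1L) stop("empty state")
  st$step <- st$step + 1L
  if (stats::runif(1) < params$pNew) {
    .growNodes(st, 2L)
    a <- st$n + 1L; b <- st$n + 2L
    st$n <- st$n + 2L
    st$adj[a] <- list(NULL); st$adj[b] <- list(NULL)
    .addEdge(st, a, b, 1, TRUE)
    st$trueDup[a] <- 1L
    st$trueDup[b] <- 1L
    st$nEvents <- st$nEvents + 1L
    .logEvent(st, "innovation", paste(a, b))
  } else {
    w <- st$deg[seq_len(st$n)] + params$alpha
    mother <- sample.int(st$n, 1L, prob = w)
    .growNodes(st, 1L)
    daughter <- st$n + 1L
    st$n <- daughter
    st$adj[daughter] <- list(NULL)
    nb <- .neighbors(st, mother)
    .addEdge(st, mother, daughter, 1, TRUE)
    st$trueDup[mother] <- st$trueDup[mother] + 1L
    st$trueDup[daughter] <- 1L
    st$nEvents <- st$nEvents + 1L
    .logEvent(st, "duplication", paste(mother, daughter))
    if (params$f > 0 && length(nb$nodes)) {
      inherit <- stats::runif(length(nb$nodes)) < params$f
      for (j in which(inherit))
        .addEdge(st, daughter, nb$nodes[j], st$eId[nb$edges[j]], FALSE)
    }
  }
  invisible(st)
}

#' Clock-like identity decay
#'
#' Decrements every surviving edge's identity by `delta`; edges falling
#' strictly below the floor (0.9) are removed from the graph.  The event
#' log and primary/secondary bookkeeping are retained for removed edges.
#'
#' @param st state environment.
#' @param delta per-step identity decrement (>= 0).
#' @param identityFloor removal threshold (default 0.9).
#' @return the state, invisibly.
#' @export
applyDecay <- function(st, delta, identityFloor = 0.9) {
  stopifnot(delta >= 0)
  if (delta == 0 || st$m == 0L) return(invisible(st))
  alive <- which(st$eAlive[seq_len(st$m)])
  st$eId[alive] <- st$eId[alive] - delta
  dead <- alive[st$eId[alive] < identityFloor]
  if (length(dead)) {
    st$eAlive[dead] <- FALSE
    for (i in dead) {
      st$deg[st$eFrom[i]] <- st$deg[st$eFrom[i]] - 1L
      st$deg[st$eTo[i]] <- st$deg[st$eTo[i]] - 1L
    }
    .logEvent(st, "loss", paste(dead, collapse = " "))
  }
  invisible(st)
}

#' Non-allelic gene conversion
#'
#' Each eligible edge independently converts with probability `rGc`: its
#' identity resets to 1 and one endpoint is designated the donor (uniformly
#' at random); for every neighbor shared by both endpoints, the acceptor's
#' edge identity to that neighbor is overwritten by the donor's, modeling
#' the copying of donor sequence into the acceptor locus.  With
#' `evasion = TRUE` removed edges (identity below 0.9) are never converted;
#' without evasion a conversion resurrects the edge.
#'
#' @param st state environment.
#' @param rGc per-edge conversion probability.
#' @param evasion do low-identity (removed) edges evade conversion?
#' @param identityFloor identity below which an edge evades conversion
#'   when `evasion` is on.
#' @return the state, invisibly.
#' @export
applyNagc <- function(st, rGc, evasion = TRUE, identityFloor = 0.9) {
  stopifnot(rGc >= 0, rGc <= 1)
  if (rGc == 0 || st$m == 0L) return(invisible(st))
  idx <- seq_len(st$m)
  eligible <- if (evasion)
    idx[st$eAlive[idx] & st$eId[idx] >= identityFloor] else idx
  if (!length(eligible)) return(invisible(st))
  conv <- eligible[stats::runif(length(eligible)) < rGc]
  for (i in conv) {
    if (!st$eAlive[i]) {   # resurrection (no-evasion scenario only)
      st$eAlive[i] <- TRUE
      st$deg[st$eFrom[i]] <- st$deg[st$eFrom[i]] + 1L
      st$deg[st$eTo[i]] <- st$deg[st$eTo[i]] + 1L
    }
    st$eId[i] <- 1
    st$eNagc[i] <- TRUE
    ends <- c(st$eFrom[i], st$eTo[i])
    donorFirst <- stats::runif(1) < 0.5
    donor <- if (donorFirst) ends[1] else ends[2]
    acceptor <- if (donorFirst) ends[2] else ends[1]
    dn <- .neighbors(st, donor)
    an <- .neighbors(st, acceptor)
    shared <- intersect(dn$nodes, an$nodes)
    shared <- shared[shared != donor & shared != acceptor]
    for (wn in shared) {
      de <- dn$edges[match(wn, dn$nodes)]
      ae <- an$edges[match(wn, an$nodes)]
      st$eId[ae] <- st$eId[de]
    }
    .logEvent(st, "nagc", paste(donor, acceptor))
  }
  invisible(st)
}

#' Simulate a PCM network with identity decay and gene conversion
#'
#' Grows a network from a single ancestral duplication to `nFinal` nodes,
#' interleaving growth, gene conversion and identity decay each step (in
#' `params$stepOrder`).  Seeded runs are bit-reproducible.
#'
#' @param params a [pcmParams()] list.
#' @param seed integer seed.
#' @return a [SimulatedNetwork-class].
#' @examples
#' net <- pcmSimulate(pcmParams(nFinal = 200, f = 0), seed = 1)
#' sum(net@edges$alive) == 200 - networkSummary(net)$n_components
#' @export
pcmSimulate <- function(params, seed = 1L) {
  stopifnot(inherits(params, "pcmParams"))
  set.seed(seed)
  st <- newPcmState()
  while (st$n < params$nFinal) {
    for (phase in params$stepOrder) {
      switch(phase,
        growth = pcmStep(st, params),
        nagc = applyNagc(st, params$rGc, params$nagcEvasion),
        decay = applyDecay(st, params$delta, params$identityFloor))
    }
  }
  idx <- seq_len(st$m)
  edges <- data.frame(
    from = st$eFrom[idx], to = st$eTo[idx],
    identity = pmin(st$eId[idx], 1),
    isPrimary = st$ePrimary[idx],
    nagcHit = st$eNagc[idx],
    alive = st$eAlive[idx]
  )
  new("SimulatedNetwork",
      nNodes = st$n,
      edges = edges,
      trueDupCount = st$trueDup[seq_len(st$n)],
      eventLog = data.frame(step = st$logStep, type = st$logType,
                            actors = st$logActors,
                            stringsAsFactors = FALSE),
      params = unclass(params))
}

#' Fraction of surviving edges affected by gene conversion
#'
#' @param net a `SimulatedNetwork`.
#' @return a number in [0, 1].
#' @export
nagcAffectedFraction <- function(net) {
  e <- net@edges
  if (!any(e$alive)) return(0)
  mean(e$nagcHit[e$alive])
}

#' Calibrate the gene-conversion rate to a target affected fraction
#'
#' Bisects on `rGc` until the mean end-of-run fraction of surviving edges
#' hit by gene conversion, over `nProbeRuns` probe simulations, falls
#' within `tol` of `targetFraction` (the human-genome estimate is 34%).
#'
#' @param params a [pcmParams()] list; its `rGc` is ignored.
#' @param targetFraction target in (0, 1), or 0 (returns 0).
#' @param nProbeRuns probe simulations per tested rate.
#' @param seed integer seed.
#' @param tol acceptable deviation of the mean fraction (default 0.02).
#' @param maxIter bisection iteration cap.
#' @return the calibrated `rGc`.
#' @export
calibrateRgc <- function(params, targetFraction = 0.34, nProbeRuns = 3,
                         seed = 1L, tol = 0.02, maxIter = 30) {
  stopifnot(targetFraction >= 0, targetFraction < 1)
  if (targetFraction == 0) return(0)
  probe <- function(r) {
    p <- params; p$rGc <- r
    mean(vapply(seq_len(nProbeRuns), function(i)
      nagcAffectedFraction(pcmSimulate(p, seed = seed + i)), numeric(1)))
  }
  hi <- 2e-4
  fHi <- probe(hi)
  tries <- 0L
  while (fHi < targetFraction && hi < 1) {
    hi <- min(1, hi * 4)
    fHi <- probe(hi)
    tries <- tries + 1L
    if (tries > 12L) break
  }
  if (fHi < targetFraction - tol)
    stop("target fraction ", targetFraction, " unattainable: rGc = ", hi,
         " reaches only ", round(fHi, 3))
  lo <- 0; fLo <- 0
  for (it in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    fMid <- probe(mid)
    if (abs(fMid - targetFraction) <= tol) return(mid)
    if (fMid < targetFraction) { lo <- mid; fLo <- fMid }
    else { hi <- mid; fHi <- fMid }
  }
  (lo + hi) / 2
}

#' @rdname accessors
#' @export
setMethod("nNodes", "SimulatedNetwork", function(x) x@nNodes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "SimulatedNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("trueDuplicationCounts", "SimulatedNetwork", function(x)
  x@trueDupCount)

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "SimulatedNetwork", function(x, ...) {
  e <- x@edges[x@edges$alive, , drop = FALSE]
  igraph::graph_from_data_frame(
    d = e[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(x@nNodes)))
})

#' @rdname networkSummary
#' @export
setMethod("networkSummary", "SimulatedNetwork", function(x, ...) {
  e <- x@edges[x@edges$alive, , drop = FALSE]
  .summaryFromEdges(e$from, e$to, x@nNodes)
})

#' @rdname detectCommunities
#' @export
setMethod("detectCommunities", "SimulatedNetwork", function(x, seed = 1L, ...) {
  .labelPropagation(asIgraph(x), seed)
})

#' @rdname cycleCensus
#' @export
setMethod("cycleCensus", "SimulatedNetwork", function(x, maxLen = 6L, ...) {
  e <- x@edges[x@edges$alive, , drop = FALSE]
  .cycleCensus(e$from, e$to, x@nNodes, maxLen)
})

#' @rdname minimumSpanningForest
#' @export
setMethod("minimumSpanningForest", "SimulatedNetwork", function(x, seed = 1L, ...) {
  e <- x@edges[x@edges$alive, , drop = FALSE]
  w <- .sharedNeighborWeights(e$from, e$to, x@nNodes)
  .forestFromEdges(e$from, e$to, w, x@nNodes, seed)
})

setMethod("show", "SimulatedNetwork", function(object) {
  s <- networkSummary(object)
  cat("SimulatedNetwork (PCM):", s$n_nodes, "nodes,", s$n_edges,
      "surviving edges,", s$n_components, "components\n")
  cat("  primary edges surviving:",
      sum(object@edges$isPrimary & object@edges$alive),
      "| NAGC-affected fraction:",
      round(nagcAffectedFraction(object), 3), "\n")
})
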