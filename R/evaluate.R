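# Accuracy evaluation of the reconstruction against simulation truth:
# edges-match and variance-explained metrics, centrality and random-tree
# baselines, and the replicated benchmark table.

#' Fraction of predicted edges that are true primary duplications
#'
#' @param predicted `data.frame` with `from`/`to` columns (e.g.
#'   [forestEdges()] of a reconstruction), a subset of the simulation's
#'   surviving edges.
#' @param truth a `SimulatedNetwork`.
#' @return percentage in [0, 100].
#' @export
edgesMatch <- function(predicted, truth) {
  if (nrow(predicted) == 0) stop("empty predicted edge set")
  e <- truth@edges[truth@edges$alive, , drop = FALSE]
  tkey <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  pkey <- paste(pmin(predicted$from, predicted$to),
                pmax(predicted$from, predicted$to))
  hit <- match(pkey, tkey)
  if (anyNA(hit))
    stop("predicted edges must be a subset of the surviving edges")
  100 * mean(e$isPrimary[hit])
}

#' Variance in true duplication counts explained by a predictor
#'
#' The squared Pearson correlation between a per-node predictor (forest
#' degrees, raw degrees, or any centrality, on whatever scale) and the true
#' per-node duplication counts.  Squared correlation is scale- and
#' location-free, which makes centralities commensurable with counts.
#'
#' @param pred numeric per-node predictor.
#' @param truth numeric per-node true counts (not constant).
#' @return R-squared in [0, 1].
#' @export
varianceExplained <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(truth) < 3) stop("need at least 3 nodes")
  if (stats::sd(truth) == 0) stop("constant truth vector")
  if (stats::sd(pred) == 0) return(0)
  stats::cor(pred, truth)^2
}

#' Per-node centrality baselines
#'
#' Computes the five centrality baselines used to benchmark the
#' reconstruction: betweenness, closeness, eigenvector, PageRank (damping
#' 0.85) and radiality.  Closeness, eigenvector and radiality are computed
#' per connected component (they are not meaningful across components) and
#' concatenated.  Radiality of node v in a component with diameter D is
#' `sum_u (D + 1 - d(v, u)) / (n_comp - 1)`.
#'
#' @param x an `SDNetwork` or `SimulatedNetwork` (or an igraph graph).
#' @return named list of numeric vectors, one value per node:
#'   `betweenness`, `closeness`, `eigenvector`, `pagerank`, `radiality`.
#' @export
centralityBaselines <- function(x) {
  g <- if (inherits(x, "igraph")) x else asIgraph(x)
  n <- igraph::vcount(g)
  out <- list(
    betweenness = as.numeric(igraph::betweenness(g)),
    closeness = numeric(n),
    eigenvector = numeric(n),
    pagerank = as.numeric(igraph::page_rank(g, damping = 0.85)$vector),
    radiality = numeric(n)
  )
  memb <- igraph::components(g)$membership
  for (comp in seq_len(max(memb))) {
    vs <- which(memb == comp)
    if (length(vs) == 1L) {
      out$closeness[vs] <- 0
      out$eigenvector[vs] <- 0
      out$radiality[vs] <- 0
      next
    }
    sub <- igraph::induced_subgraph(g, vs)
    out$closeness[vs] <- as.numeric(igraph::closeness(sub, normalized = TRUE))
    out$eigenvector[vs] <- as.numeric(igraph::eigen_centrality(sub)$vector)
    d <- igraph::distances(sub)
    diam <- max(d)
    out$radiality[vs] <- rowSums(diam + 1 - d) / (length(vs) - 1)
  }
  out
}

#' Random spanning forest baseline
#'
#' Draws one spanning forest by running Kruskal on i.i.d. uniform random
#' edge weights — a cheap, seeded stand-in for uniform spanning-tree
#' sampling, sufficient as a baseline.
#'
#' @param x an `SDNetwork` or `SimulatedNetwork`.
#' @param seed integer seed.
#' @return a [SpanningForest-class].
#' @export
randomSpanningForest <- function(x, seed = 1L) {
  el <- .edgeEndpoints(x)
  set.seed(seed)
  w <- stats::runif(length(el$from))
  .forestFromEdges(el$from, el$to, w, el$n, seed = seed + 1L)
}

#' Benchmark reconstruction strategies on simulated networks
#'
#' For each replicate: simulate a PCM network (with decay and gene
#' conversion as configured in `params`), predict the primary events /
#' duplication counts with each method, and score them with
#' [edgesMatch()] (where an edge set is predicted) and
#' [varianceExplained()].  Methods: the shared-neighbor-weighted minimum
#' spanning forest (`mst`), the raw node degree vector (`degrees`), a
#' random spanning forest (`random_tree`), and the five centralities.
#'
#' @param params a [pcmParams()] list.
#' @param nReps number of simulation replicates.
#' @param seed integer seed.
#' @param methods subset of methods to run (default all).
#' @return `data.frame`: `method`, `edges_match` (mean %, NA for
#'   vector-only methods), `edges_match_se`, `r2` (mean), `r2_se`.
#' @export
benchmarkReconstruction <- function(params, nReps = 20, seed = 1L,
                                    methods = c("mst", "degrees",
                                                "random_tree", "betweenness",
                                                "closeness", "eigenvector",
                                                "pagerank", "radiality")) {
  stopifnot(nReps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  match_ <- list(); r2_ <- list()
  for (m in methods) { match_[[m]] <- numeric(0); r2_[[m]] <- numeric(0) }
  needCent <- any(methods %in% c("betweenness", "closeness", "eigenvector",
                                 "pagerank", "radiality"))
  for (rep in seq_len(nReps)) {
    sim <- pcmSimulate(params, seed = seed + rep)
    truthCounts <- trueDuplicationCounts(sim)
    cent <- if (needCent) centralityBaselines(sim) else NULL
    for (m in methods) {
      if (m == "mst") {
        fo <- minimumSpanningForest(sim, seed = seed + 1000L + rep)
        match_[[m]] <- c(match_[[m]], edgesMatch(forestEdges(fo), sim))
        r2_[[m]] <- c(r2_[[m]],
                      varianceExplained(duplicationCounts(fo), truthCounts))
      } else if (m == "random_tree") {
        fo <- randomSpanningForest(sim, seed = seed + 2000L + rep)
        match_[[m]] <- c(match_[[m]], edgesMatch(forestEdges(fo), sim))
        r2_[[m]] <- c(r2_[[m]],
                      varianceExplained(duplicationCounts(fo), truthCounts))
      } else if (m == "degrees") {
        e <- sim@edges[sim@edges$alive, , drop = FALSE]
        deg <- tabulate(c(e$from, e$to), nNodes(sim))
        r2_[[m]] <- c(r2_[[m]], varianceExplained(deg, truthCounts))
      } else {
        r2_[[m]] <- c(r2_[[m]], varianceExplained(cent[[m]], truthCounts))
      }
    }
  }
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  data.frame(
    method = methods,
    edges_match = vapply(methods, function(m)
      if (length(match_[[m]])) mean(match_[[m]]) else NA_real_, numeric(1)),
    edges_match_se = vapply(methods, function(m)
      if (length(match_[[m]])) se(match_[[m]]) else NA_real_, numeric(1)),
    r2 = vapply(methods, function(m) mean(r2_[[m]]), numeric(1)),
    r2_se = vapply(methods, function(m) se(r2_[[m]]), numeric(1)),
    row.names = NULL
  )
}
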