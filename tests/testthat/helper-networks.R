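# Shared test helpers: small graphs and alignment tables built in code.

# alignment record table from a compact spec: each row
# chromA,startA,endA,chromB,startB,endB,identity (0-based half-open)
makeRecords <- function(...) {
  rows <- list(...)
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r)
    data.frame(chromA = r[[1]], startA = as.numeric(r[[2]]),
               endA = as.numeric(r[[3]]), chromB = r[[4]],
               startB = as.numeric(r[[5]]), endB = as.numeric(r[[6]]),
               identity = as.numeric(r[[7]])))))
  df$id <- paste0("A", seq_len(nrow(df)))
  df[, c("id", "chromA", "startA", "endA", "chromB", "startB", "endB",
         "identity")]
}

# a SimulatedNetwork wrapping a plain edge list (all edges alive and
# primary unless stated) — used to drive graph algorithms with known
# topology
graphAsSim <- function(from, to, n = max(c(from, to)),
                       primary = rep(TRUE, length(from)),
                       identity = rep(1, length(from))) {
  new("SimulatedNetwork",
      nNodes = as.integer(n),
      edges = data.frame(from = as.integer(from), to = as.integer(to),
                         identity = identity, isPrimary = primary,
                         nagcHit = rep(FALSE, length(from)),
                         alive = rep(TRUE, length(from))),
      trueDupCount = tabulate(c(from, to), n),
      eventLog = data.frame(step = integer(0), type = character(0),
                            actors = character(0)),
      params = list())
}

# exhaustive minimum spanning forest weight by enumerating all edge
# subsets of size n - c (oracle for Kruskal)
bruteForestWeight <- function(from, to, weight, n) {
  g0 <- igraph::graph_from_data_frame(data.frame(from, to),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  nc <- igraph::components(g0)$no
  k <- n - nc
  if (k == 0) return(0)
  best <- Inf
  for (sel in utils::combn(length(from), k, simplify = FALSE)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = from[sel], to = to[sel]), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    if (igraph::components(g)$no == nc && !igraph::any_loop(g) &&
        length(igraph::girth(g)$circle) == 0)
      best <- min(best, sum(weight[sel]))
  }
  best
}

# all spanning trees of a small connected graph, as lists of edge indices
allSpanningTrees <- function(from, to, n) {
  out <- list()
  for (sel in utils::combn(length(from), n - 1, simplify = FALSE)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = from[sel], to = to[sel]), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    if (igraph::is_connected(g) && length(igraph::girth(g)$circle) == 0)
      out[[length(out) + 1L]] <- sel
  }
  out
}
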