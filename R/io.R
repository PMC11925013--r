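# Table writers for networks, forests and simulations (TSV + JSON
# summaries; genomic coordinates written back 0-based half-open).

#' Write a duplication network to a directory
#'
#' Emits `nodes.tsv` (id, chrom, start, end — 0-based half-open — degree,
#' self_loops, double_edges, component, community), `edges.tsv` (node_a,
#' node_b, n_alignments, max_identity, intrachromosomal, suspicious,
#' weight) and `summary.json`.
#'
#' @param net an `SDNetwork`.
#' @param dir output directory (created if needed).
#' @param seed seed for the community detection recorded in the table.
#' @return invisibly, the file paths.
#' @export
exportNetwork <- function(net, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- edgeTable(net)
  reg <- regions(net)
  n <- nNodes(net)
  deg <- tabulate(c(e$nodeA, e$nodeB), n)
  comp <- if (nrow(e)) .components(e$nodeA, e$nodeB, n) else seq_len(n)
  comm <- detectCommunities(net, seed = seed)
  nodes <- data.frame(
    id = mcols(reg)$node,
    chrom = as.character(seqnames(reg)),
    start = start(reg) - 1,
    end = end(reg),
    degree = deg,
    self_loops = selfLoops(net),
    double_edges = doubleEdges(net),
    component = comp,
    community = comm
  )
  paths <- list(nodes = file.path(dir, "nodes.tsv"),
                edges = file.path(dir, "edges.tsv"),
                summary = file.path(dir, "summary.json"))
  utils::write.table(nodes, paths$nodes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(node_a = e$nodeA, node_b = e$nodeB,
               n_alignments = e$nAlignments, max_identity = e$maxIdentity,
               intrachromosomal = e$intrachromosomal,
               suspicious = e$suspicious, weight = e$weight),
    paths$edges, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(networkSummary(net), paths$summary,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a spanning forest to a directory
#'
#' Emits `forest_edges.tsv` (node_a, node_b, weight) and `counts.tsv`
#' (node, duplications).
#'
#' @param forest a `SpanningForest`.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
exportForest <- function(forest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(edges = file.path(dir, "forest_edges.tsv"),
                counts = file.path(dir, "counts.tsv"))
  e <- forestEdges(forest)
  utils::write.table(
    data.frame(node_a = e$from, node_b = e$to, weight = e$weight),
    paths$edges, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node = seq_len(nNodes(forest)),
               duplications = duplicationCounts(forest)),
    paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a simulated network with its truth labels
#'
#' Emits `sim_edges.tsv` (node_a, node_b, identity, is_primary, nagc_hit,
#' alive), `sim_nodes.tsv` (node, true_duplications) and
#' `sim_events.json`.
#'
#' @param sim a `SimulatedNetwork`.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
exportSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(edges = file.path(dir, "sim_edges.tsv"),
                nodes = file.path(dir, "sim_nodes.tsv"),
                events = file.path(dir, "sim_events.json"))
  e <- edgeTable(sim)
  utils::write.table(
    data.frame(node_a = e$from, node_b = e$to, identity = e$identity,
               is_primary = e$isPrimary, nagc_hit = e$nagcHit,
               alive = e$alive),
    paths$edges, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node = seq_len(nNodes(sim)),
               true_duplications = trueDuplicationCounts(sim)),
    paths$nodes, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim@eventLog, paths$events, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
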