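library(GenomicRanges)

test_that("regions are transitive unions of overlapping intervals", {
  rec <- makeRecords(
    list("chr1", 100, 2000, "chr2", 0, 1500, 0.95),
    list("chr1", 1500, 3000, "chr3", 0, 1500, 0.96))
  reg <- buildDuplicatedRegions(rec)
  chr1 <- reg[seqnames(reg) == "chr1"]
  expect_equal(length(chr1), 1)
  expect_equal(start(chr1), 101)   # 0-based 100 -> 1-based 101
  expect_equal(end(chr1), 3000)

  # independent oracle: sweep over sorted endpoints
  ivs <- rbind(c(100, 2000), c(1500, 3000))
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  merged <- list(ivs[1, ])
  for (i in seq_len(nrow(ivs))[-1]) {
    last <- merged[[length(merged)]]
    if (ivs[i, 1] < last[2]) merged[[length(merged)]] <-
        c(last[1], max(last[2], ivs[i, 2]))
    else merged[[length(merged) + 1]] <- ivs[i, ]
  }
  expect_equal(length(merged), 1)
  expect_equal(merged[[1]], c(100, 3000))
})

test_that("disjoint and bookended intervals stay separate", {
  rec <- makeRecords(
    list("chr1", 0, 1000, "chr2", 0, 1000, 0.95),
    list("chr1", 1000, 2000, "chr3", 0, 1000, 0.95))  # touching, no overlap
  reg <- buildDuplicatedRegions(rec)
  expect_equal(sum(seqnames(reg) == "chr1"), 2)
})

test_that("region building is idempotent on its own output", {
  set.seed(5)
  rec <- makeRecords(
    list("chr1", 100, 2000, "chr1", 1800, 4000, 0.95),
    list("chr1", 3900, 6000, "chr2", 0, 2100, 0.96),
    list("chr2", 2000, 4000, "chr3", 500, 2500, 0.97))
  reg <- buildDuplicatedRegions(rec)
  # feed the region intervals back in as both sides of fake alignments
  rec2 <- data.frame(id = paste0("B", seq_along(reg)),
                     chromA = as.character(seqnames(reg)),
                     startA = start(reg) - 1, endA = end(reg),
                     chromB = as.character(seqnames(reg)),
                     startB = start(reg) - 1, endB = end(reg),
                     identity = 0.95)
  reg2 <- buildDuplicatedRegions(rec2)
  expect_equal(as.character(seqnames(reg2)), as.character(seqnames(reg)))
  expect_equal(start(reg2), start(reg))
  expect_equal(end(reg2), end(reg))
})

test_that("the two-duplication overlap scenario gives 3 nodes and 3 edges", {
  # event 1: P -> Q; event 2 sources inside Q -> R, implying a secondary
  # P~R alignment: three regions, two primary + one secondary edge
  rec <- makeRecords(
    list("chr1", 0, 10000, "chr2", 0, 10000, 0.95),       # P -> Q
    list("chr2", 2000, 8000, "chr3", 0, 6000, 0.99),      # Q-part -> R
    list("chr1", 2000, 8000, "chr3", 0, 6000, 0.94))      # secondary P~R
  net <- buildNetwork(buildDuplicatedRegions(rec), rec)
  expect_equal(nNodes(net), 3)
  expect_equal(nrow(edgeTable(net)), 3)
  expect_equal(networkSummary(net)$n_components, 1)
})

test_that("self-loops and parallel alignments are trimmed but counted", {
  rec <- makeRecords(
    list("chr1", 0, 5000, "chr1", 3000, 9000, 0.95),   # overlapping copies:
    list("chr2", 0, 5000, "chr3", 0, 5000, 0.92),      # one region, self-loop
    list("chr2", 100, 5100, "chr3", 100, 5100, 0.98))  # parallel pair
  net <- buildNetwork(buildDuplicatedRegions(rec), rec)
  expect_equal(nNodes(net), 3)   # chr1 union, chr2, chr3
  e <- edgeTable(net)
  expect_equal(nrow(e), 1)
  expect_equal(e$nAlignments, 2L)
  expect_equal(e$maxIdentity, 0.98)
  expect_equal(sum(selfLoops(net)), 1L)
  expect_equal(sum(doubleEdges(net)), 2L)  # both endpoints of the multi-edge
  # every alignment is accounted for exactly once
  expect_equal(sum(e$nAlignments) + sum(selfLoops(net)), nrow(rec))
})

test_that("summary reports components, giant shares, and the forest size law", {
  sim <- graphAsSim(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), n = 6)
  s <- networkSummary(sim)   # two disjoint triangles
  expect_equal(s$n_components, 2)
  expect_equal(s$giant_node_share, 50.0)
  # N - C edges in any spanning forest
  fo <- minimumSpanningForest(sim)
  expect_equal(nrow(forestEdges(fo)), s$n_nodes - s$n_components)
  empty <- networkSummary(graphAsSim(integer(0), integer(0), n = 0))
  expect_equal(empty$n_nodes, 0)
  expect_equal(empty$n_components, 0)
})

test_that("intrachromosomal edges are flagged from the region chromosomes", {
  rec <- makeRecords(
    list("chr1", 0, 2000, "chr1", 10000, 12000, 0.95),
    list("chr1", 0, 2000, "chr2", 0, 2000, 0.95))
  net <- buildNetwork(buildDuplicatedRegions(rec), rec)
  e <- edgeTable(net)
  expect_equal(sort(e$intrachromosomal), c(FALSE, TRUE))
})

test_that("label propagation splits a barbell and respects components", {
  # two K5 cliques joined by one bridge edge
  k5 <- t(utils::combn(5, 2))
  from <- c(k5[, 1], k5[, 1] + 5, 1)
  to <- c(k5[, 2], k5[, 2] + 5, 6)
  sim <- graphAsSim(from, to, n = 10)
  memb <- detectCommunities(sim, seed = 3)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:5])), 1)
  expect_equal(length(unique(memb[6:10])), 1)

  # partition is invariant under node relabeling (up to label names)
  perm <- c(6:10, 1:5)
  sim2 <- graphAsSim(perm[from], perm[to], n = 10)
  memb2 <- detectCommunities(sim2, seed = 3)
  expect_equal(length(unique(memb2)), 2)
  agree <- outer(memb, memb, "==") == outer(memb2[perm], memb2[perm], "==")
  expect_true(all(agree))

  # communities never span components; labels cover every node
  sim3 <- graphAsSim(c(1, 2, 4, 5), c(2, 3, 5, 6), n = 6)
  m3 <- detectCommunities(sim3, seed = 1)
  expect_equal(length(m3), 6)
  comp <- igraph::components(asIgraph(sim3))$membership
  tab <- table(m3, comp)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("intervals map to the node with the longest overlap", {
  rec <- makeRecords(
    list("chr1", 0, 1000, "chr2", 0, 1000, 0.95),
    list("chr1", 2000, 4000, "chr3", 0, 2000, 0.95))
  net <- buildNetwork(buildDuplicatedRegions(rec), rec)
  # query overlaps node 1 by 300 bp and node 2 by 800 bp
  q <- GRanges(c("chr1", "chr1", "chr4"),
               IRanges(c(701, 701, 1), c(2800, 1000, 100)))
  res <- mapIntervalsToNodes(net, q)
  reg <- regions(net)
  n1 <- which(start(reg) == 1 & as.character(seqnames(reg)) == "chr1")
  n2 <- which(start(reg) == 2001 & as.character(seqnames(reg)) == "chr1")
  expect_equal(res$node[1], n2)
  expect_equal(res$overlap[1], 800)
  expect_equal(res$node[2], n1)
  expect_true(is.na(res$node[3]))   # no overlap -> unassigned
  expect_false(any(res$tie, na.rm = TRUE))
})

test_that("exact overlap ties break to the lowest (chrom, start) node", {
  rec <- makeRecords(
    list("chr1", 0, 1000, "chr2", 0, 1000, 0.95),
    list("chr1", 2000, 3000, "chr3", 0, 1000, 0.95))
  net <- buildNetwork(buildDuplicatedRegions(rec), rec)
  # overlaps both chr1 nodes by exactly 500 bp
  q <- GRanges("chr1", IRanges(501, 2500))
  res <- mapIntervalsToNodes(net, q)
  reg <- regions(net)
  expect_equal(res$node,
               which(as.character(seqnames(reg)) == "chr1" & start(reg) == 1))
  expect_true(res$tie)
})

test_that("matching breakpoints mark edges suspicious unless a gap excuses them", {
  # node P aligned to two partners, both alignments ending at the same
  # coordinate on P
  rec <- makeRecords(
    list("chr1", 0, 5000, "chr2", 0, 5000, 0.95),
    list("chr1", 1000, 5000, "chr3", 0, 4000, 0.95))
  net <- buildNetwork(buildDuplicatedRegions(rec), rec)
  flagged <- flagSuspiciousEdges(net, gaps = GRanges())
  expect_true(all(edgeTable(flagged)$suspicious))

  # a gap abutting the shared breakpoint (within 50 bp) excuses it
  gap <- GRanges("chr1", IRanges(5010, 6000))
  excused <- flagSuspiciousEdges(net, gaps = gap)
  expect_false(any(edgeTable(excused)$suspicious))

  # coordinates differing by tol + 1 do not match
  rec2 <- makeRecords(
    list("chr1", 0, 5000, "chr2", 0, 5000, 0.95),
    list("chr1", 1000, 5003, "chr3", 0, 4003, 0.95))
  net2 <- buildNetwork(buildDuplicatedRegions(rec2), rec2)
  expect_false(any(edgeTable(
    flagSuspiciousEdges(net2, tolBp = 2))$suspicious))
  expect_true(all(edgeTable(
    flagSuspiciousEdges(net2, tolBp = 3))$suspicious))
})

test_that("cycle census counts chordless cycles and shortest self-paths", {
  tri <- graphAsSim(c(1, 2, 3), c(2, 3, 1))
  cc <- cycleCensus(tri, maxLen = 5)
  expect_equal(unname(cc$cycles["3"]), 1L)
  expect_equal(cc$shortestSelfPath, c(3, 3, 3))

  tree <- graphAsSim(c(1, 1, 2), c(2, 3, 4))
  cct <- cycleCensus(tree, maxLen = 5)
  expect_true(all(cct$cycles == 0))
  expect_true(all(is.infinite(cct$shortestSelfPath)))

  # K4: every 4-cycle has a chord, so only the four triangles remain;
  # verified against exhaustive enumeration of vertex subsets
  k4 <- t(utils::combn(4, 2))
  sim <- graphAsSim(k4[, 1], k4[, 2])
  cc4 <- cycleCensus(sim, maxLen = 6)
  nTriBrute <- sum(apply(utils::combn(4, 3), 2, function(v) 1))
  expect_equal(unname(cc4$cycles["3"]), nTriBrute)
  expect_true(all(cc4$cycles[c("4", "5", "6")] == 0))

  # a chordless 5-cycle is found at its length
  c5 <- graphAsSim(1:5, c(2:5, 1))
  expect_equal(unname(cycleCensus(c5, maxLen = 6)$cycles["5"]), 1L)
  expect_error(cycleCensus(tri, maxLen = 2), "at least 3")
})
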