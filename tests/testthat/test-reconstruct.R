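test_that("shared-neighbor weights follow the formula and its bounds", {
  # N(a) = {b, c, d}, N(b) = {a, c, e}: shared {c}, min degree 3 -> 2/3
  # nodes: a=1 b=2 c=3 d=4 e=5
  sim <- graphAsSim(c(1, 1, 1, 2, 2), c(2, 3, 4, 3, 5))
  expect_equal(edgeWeight(sim, 1, 2), 2 / 3)
  # endpoints sharing no neighbors -> exactly 1
  expect_equal(edgeWeight(sim, 1, 4), 1)
  expect_error(edgeWeight(sim, 3, 3), "itself")
  expect_error(edgeWeight(sim, 4, 5), "not in the network")

  # bounds (0, 1] on random graphs; w = 1 iff no shared neighbors
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.4
    if (sum(keep) < 2) next
    from <- pairs[keep, 1]; to <- pairs[keep, 2]
    s <- graphAsSim(from, to, n = n)
    adj <- lapply(seq_len(n), function(v)
      c(to[from == v], from[to == v]))
    for (j in seq_along(from)) {
      w <- edgeWeight(s, from[j], to[j])
      expect_gt(w, 0)
      expect_lte(w, 1)
      shared <- length(intersect(adj[[from[j]]], adj[[to[j]]]))
      expect_equal(w == 1, shared == 0)
    }
  }
})

test_that("adding a shared neighbor never increases an edge weight", {
  # monotonicity: start from a-b plus separate neighbors, then connect a
  # common neighbor to both endpoints
  base <- graphAsSim(c(1, 1, 2), c(2, 3, 4))
  w0 <- edgeWeight(base, 1, 2)
  plus <- graphAsSim(c(1, 1, 2, 1, 2), c(2, 3, 4, 5, 5))
  w1 <- edgeWeight(plus, 1, 2)
  expect_lte(w1, w0)
})

test_that("suspicious penalty keeps flagged edges out when alternatives exist", {
  rec <- makeRecords(
    list("chr1", 0, 5000, "chr2", 0, 5000, 0.95),
    list("chr2", 1000, 5000, "chr3", 0, 4000, 0.96),
    list("chr1", 1000, 5000, "chr3", 0, 4000, 0.94))
  net <- buildNetwork(buildDuplicatedRegions(rec), rec)
  expect_error(minimumSpanningForest(net), "assign weights")
  # force exactly one edge suspicious and verify exclusion against the
  # enumeration of the three spanning trees of a triangle
  net@edges$suspicious <- c(FALSE, FALSE, TRUE)
  net <- assignWeights(net, suspiciousPenalty = 2)
  e <- edgeTable(net)
  expect_true(all(e$weight[1:2] <= 1 & e$weight[1:2] > 0))
  expect_equal(e$weight[3], 2)
  fo <- minimumSpanningForest(net, seed = 1)
  fe <- forestEdges(fo)
  key <- paste(fe$from, fe$to)
  expect_false(paste(e$nodeA[3], e$nodeB[3]) %in% key)
  trees <- allSpanningTrees(e$nodeA, e$nodeB, 3)
  wts <- vapply(trees, function(s) sum(e$weight[s]), numeric(1))
  expect_equal(sum(fe$weight), min(wts))
  expect_error(assignWeights(net, suspiciousPenalty = 1), "exceed 1")
})

test_that("an all-suspicious component still spans, with a warning", {
  rec <- makeRecords(list("chr1", 0, 5000, "chr2", 0, 5000, 0.95))
  net <- buildNetwork(buildDuplicatedRegions(rec), rec)
  net@edges$suspicious <- TRUE
  net <- assignWeights(net)
  expect_warning(fo <- minimumSpanningForest(net), "suspicious")
  expect_equal(nrow(forestEdges(fo)), 1)
})

test_that("a triangle's heaviest edge is excluded", {
  sim <- graphAsSim(c(1, 2, 3), c(2, 3, 1))
  fo <- .forestFromEdges(c(1, 2, 3), c(2, 3, 1), c(0.2, 0.3, 0.5), 3, seed = 1)
  fe <- forestEdges(fo)
  expect_equal(sort(fe$weight), c(0.2, 0.3))
})

test_that("Kruskal equals the exhaustive minimum on small random graphs", {
  set.seed(9)
  for (i in 1:40) {
    n <- sample(4:7, 1)
    pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.55
    if (sum(keep) < n - 2) next
    from <- pairs[keep, 1]; to <- pairs[keep, 2]
    w <- round(runif(length(from)), 2)   # rounded -> frequent ties
    fo <- .forestFromEdges(from, to, w, n, seed = i)
    expect_equal(sum(forestEdges(fo)$weight),
                 bruteForestWeight(from, to, w, n), tolerance = 1e-12)
    # cross-check against igraph's MST total weight
    g <- igraph::graph_from_data_frame(
      data.frame(from, to, weight = w), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    expect_equal(sum(forestEdges(fo)$weight),
                 sum(igraph::E(igraph::mst(g))$weight), tolerance = 1e-12)
    # invariants: |E| = N - C, acyclic, spanning, degree sum
    nc <- igraph::components(g)$no
    expect_equal(nrow(forestEdges(fo)), n - nc)
    expect_equal(sum(duplicationCounts(fo)), 2 * nrow(forestEdges(fo)))
  }
})

test_that("a tree input is returned unchanged regardless of weights", {
  from <- c(1, 1, 2, 4); to <- c(2, 3, 4, 5)
  fo <- .forestFromEdges(from, to, c(10, 20, 30, 40), 5, seed = 2)
  expect_equal(nrow(forestEdges(fo)), 4)
  expect_equal(sort(duplicationCounts(fo)), c(1L, 1L, 2L, 2L, 2L))
})

test_that("duplication counts are forest degrees", {
  # path a-b-c -> 1, 2, 1; star center gets k; isolated node 0
  path <- .forestFromEdges(c(1, 2), c(2, 3), c(1, 1), 3, seed = 1)
  expect_equal(duplicationCounts(path), c(1L, 2L, 1L))
  star <- .forestFromEdges(rep(1, 4), 2:5, rep(1, 4), 6, seed = 1)
  expect_equal(duplicationCounts(star), c(4L, 1L, 1L, 1L, 1L, 0L))
})

test_that("forest tie-breaking is seeded and reproducible", {
  k4 <- t(utils::combn(4, 2))
  w <- rep(0.5, 6)
  f1 <- .forestFromEdges(k4[, 1], k4[, 2], w, 4, seed = 7)
  f2 <- .forestFromEdges(k4[, 1], k4[, 2], w, 4, seed = 7)
  expect_identical(forestEdges(f1), forestEdges(f2))
  # different seeds reach different (equally minimal) trees eventually
  picks <- vapply(1:20, function(s)
    paste(sort(paste(forestEdges(
      .forestFromEdges(k4[, 1], k4[, 2], w, 4, seed = s))$from,
      forestEdges(.forestFromEdges(k4[, 1], k4[, 2], w, 4,
                                   seed = s))$to)), collapse = ";"),
    character(1))
  expect_gt(length(unique(picks)), 1)
})

test_that("enrichment p-values agree with exhaustive enumeration", {
  # toy: 5-node path forest (4 edges, all identity 1) plus 6 non-forest
  # edges of which 2 have identity 1; predicate = identity > 0.99
  from <- c(1, 2, 3, 4,  1, 1, 1, 2, 2, 3)
  to <- c(2, 3, 4, 5,  3, 4, 5, 4, 5, 5)
  ident <- c(rep(1, 4), 1, 0.95, 0.95, 1, 0.95, 0.95)
  sim <- graphAsSim(from, to, identity = ident)
  fo <- .forestFromEdges(from[1:4], to[1:4], rep(0.5, 4), 5, seed = 1)
  pred <- function(e) e$identity > 0.99
  obs <- 4
  # exhaustive: all C(6, 4) = 15 draws from the pool; count >= 4 requires
  # taking both identity-1 pool edges plus any 2 of the 4 others ->
  # impossible to reach 4 (max count = 2): exact tail probability = 0
  pool <- ident[5:10]
  draws <- utils::combn(6, 4, simplify = FALSE)
  tailProb <- mean(vapply(draws, function(d)
    sum(pool[d] > 0.99) >= obs, logical(1)))
  expect_equal(tailProb, 0)
  res <- mstEnrichmentTest(sim, fo, pred, "greater", nRounds = 2000,
                           seed = 11)
  expect_equal(res$observed, obs)
  expect_equal(res$p, (1 + 2000 * tailProb) / 2001, tolerance = 1e-12)

  # a draw with a non-trivial exact tail: forest has 2 qualifying edges,
  # pool has 2 of 6; P(pool draw of 4 has >= 2) = C(2,2) C(4,2) / C(6,4)
  ident2 <- c(1, 1, 0.95, 0.95, ident[5:10])
  simB <- graphAsSim(from, to, identity = ident2)
  tailB <- mean(vapply(draws, function(d)
    sum(pool[d] > 0.99) >= 2, logical(1)))
  expect_equal(tailB, 6 / 15)
  resB <- mstEnrichmentTest(simB, fo, pred, "greater", nRounds = 4000,
                            seed = 5)
  expect_equal(resB$observed, 2)
  expect_equal(resB$p, tailB, tolerance = 0.05)

  # a non-degenerate case: predicate = identity >= 0.95 everywhere is
  # satisfied by every edge, so depletion has p = 1 as well
  resLess <- mstEnrichmentTest(sim, fo, function(e) e$identity >= 0.95,
                               "less", nRounds = 200, seed = 3)
  expect_equal(resLess$p, 1)
  # fewer non-forest edges than forest edges errors
  foAll <- .forestFromEdges(from, to, rep(1, 10), 5, seed = 1)
  expect_equal(nrow(forestEdges(foAll)), 4)
  sim2 <- graphAsSim(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  fo2 <- .forestFromEdges(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6),
                          rep(1, 5), 6, seed = 1)
  expect_error(mstEnrichmentTest(sim2, fo2, pred, "greater"),
               "fewer non-forest")
})

test_that("enrichment p matches brute force on a tiny instance", {
  # 4-node clique: forest = 3 edges, pool = 3 non-forest edges;
  # predicate marks 2 specific edges
  k4 <- t(utils::combn(4, 2))
  ident <- c(1, 1, 0.95, 0.95, 0.95, 0.92)
  sim <- graphAsSim(k4[, 1], k4[, 2], identity = ident)
  w <- c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9)
  fo <- .forestFromEdges(k4[, 1], k4[, 2], w, 4, seed = 1)
  pred <- function(e) e$identity > 0.99
  obs <- sum(ident[1:3] > 0.99)   # forest = first three edges
  # brute force over all C(3,3) = 1 draws of the pool
  poolCount <- sum(ident[4:6] > 0.99)
  pExact <- (1 + as.numeric(poolCount >= obs)) / 2
  res <- mstEnrichmentTest(sim, fo, pred, "greater", nRounds = 1, seed = 1)
  expect_equal(res$p, pExact)
  # extreme case: predicate true only on forest edges, many rounds
  res2 <- mstEnrichmentTest(sim, fo, pred, "greater", nRounds = 10000,
                            seed = 1)
  expect_equal(res2$p, 1 / 10001)
  # predicate true everywhere -> p = 1 for enrichment
  resAll <- mstEnrichmentTest(sim, fo, function(e) rep(TRUE, nrow(e)),
                              "greater", nRounds = 50, seed = 1)
  expect_equal(resAll$p, 1)
})
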