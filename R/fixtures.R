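# Fully synthetic test genome: forward-simulates duplication events on
# coordinates and emits an SD annotation table, truth labels, and feature
# tracks with planted effects, so the whole pipeline is testable with
# known ground truth and no downloads.

#' Parameters for the synthetic duplication fixture
#'
#' @param nChroms number of chromosomes.
#' @param chromLengthBp length of each chromosome.
#' @param nDuplicationEvents duplication events to simulate.
#' @param dupLenMin,dupLenMean minimum and mean duplication length (bp;
#'   lengths are `dupLenMin` plus an exponential excess).
#' @param overlapProb probability that an event's source lies inside an
#'   existing duplicated copy, which yields an additional secondary
#'   alignment (the overlap mechanism behind cycles in the network).
#' @param breakpointRepeatEnrichment fold enrichment of the planted
#'   repeat family just outside copy breakpoints, relative to its genomic
#'   background density.
#' @param featureAssociationStrength correlation strength (0..1) between
#'   the planted value track and a locus's true duplication count.
#' @param nBackgroundRepeats background repeat intervals per family.
#' @param seed integer seed.
#' @return a `fixtureParams` list.
#' @export
fixtureParams <- function(nChroms = 4, chromLengthBp = 2e7,
                          nDuplicationEvents = 120,
                          dupLenMin = 1000, dupLenMean = 8000,
                          overlapProb = 0.3,
                          breakpointRepeatEnrichment = 20,
                          featureAssociationStrength = 0.5,
                          nBackgroundRepeats = 1500,
                          seed = 1L) {
  stopifnot(nChroms >= 1, chromLengthBp >= 1e5, nDuplicationEvents >= 0,
            dupLenMin >= 1000, dupLenMean >= dupLenMin,
            overlapProb >= 0, overlapProb <= 1,
            featureAssociationStrength >= 0, featureAssociationStrength <= 1)
  structure(as.list(environment()), class = "fixtureParams")
}

#' Generate a synthetic duplication fixture
#'
#' Simulates `nDuplicationEvents` duplications: each copies a source
#' interval to a fresh target locus and emits one primary alignment.
#' With probability `overlapProb` the source is placed inside an existing
#' copy, in which case the homology implied by the earlier event is also
#' emitted as one secondary alignment (between the corresponding part of
#' the earlier copy's partner and the new copy) when it is at least 1 kbp
#' long.  Event identities decrease linearly with age from 1.0 towards
#' 0.9, mimicking the molecular clock.  A repeat family is planted at
#' copy breakpoints at `breakpointRepeatEnrichment` times its background
#' density, and a value track is generated whose value at a locus
#' correlates with the locus's true duplication count at the stated
#' strength.
#'
#' @param params a [fixtureParams()] list.
#' @param outDir optional directory; when given, all tables are written
#'   in the dialects the parsers consume (SD table as 7-column TSV with
#'   0-based half-open coordinates, BED3 repeats/gaps, bedGraph value
#'   tracks, chrom sizes, centromere/telomere table, truth TSV).
#' @return a list bundle: `records` (alignment table in
#'   [parseSdAnnotation()] layout), `truth` (`data.frame` with
#'   `isPrimary`, `event`), `gaps`, `repeats` (named list of `GRanges`),
#'   `tracks` (named list of `GRanges` with `score`), `chromSizes`,
#'   `centromeres`, `telomeres`, `params`, and `files` (paths, when
#'   written).
#' @export
generateFixture <- function(params, outDir = NULL) {
  stopifnot(inherits(params, "fixtureParams"))
  set.seed(params$seed)
  chroms <- paste0("chr", seq_len(params$nChroms))
  chromSizes <- stats::setNames(rep(params$chromLengthBp, params$nChroms),
                                chroms)
  totalBp <- sum(chromSizes)
  if (params$nDuplicationEvents * params$dupLenMean * 3 > totalBp)
    stop("genome too small for the requested number of events")

  # assembly gaps: 2 per chromosome
  gapL <- 5e4
  gaps <- suppressWarnings(do.call(c, lapply(chroms, function(ch) {
    s <- sort(sample.int(params$chromLengthBp - gapL, 2))
    GRanges(ch, IRanges(s, s + gapL - 1))
  })))

  occupied <- gaps   # copies must avoid gaps and (for fresh loci) each other
  placeFresh <- function(len) {
    for (try in 1:500) {
      ch <- sample(chroms, 1)
      s <- sample.int(chromSizes[ch] - len, 1)
      cand <- GRanges(ch, IRanges(s, s + len - 1))
      if (!suppressWarnings(IRanges::overlapsAny(cand, occupied,
                                                 maxgap = 100)))
        return(cand)
    }
    stop("genome too small: could not place a fresh locus of length ", len)
  }

  nEv <- params$nDuplicationEvents
  recs <- vector("list", 0)
  # copies ledger: interval of every copy plus the event that made it and
  # its partner interval (for projecting overlaps)
  copies <- GRanges()
  copySrc <- GRanges()    # parallel: the source the copy was made from
  identityOf <- function(ev) if (nEv <= 1) 0.99 else
    0.901 + 0.098 * (ev - 1) / (nEv - 1)

  addRecord <- function(grA, grB, ident, primary, ev) {
    recs[[length(recs) + 1L]] <<- data.frame(
      chromA = as.character(seqnames(grA)), startA = start(grA) - 1,
      endA = end(grA), chromB = as.character(seqnames(grB)),
      startB = start(grB) - 1, endB = end(grB),
      identity = round(ident, 4), isPrimary = primary, event = ev,
      stringsAsFactors = FALSE)
  }

  for (ev in seq_len(nEv)) {
    len <- params$dupLenMin +
      round(stats::rexp(1, 1 / (params$dupLenMean - params$dupLenMin)))
    useOverlap <- length(copies) > 0 && stats::runif(1) < params$overlapProb
    parent <- NULL
    if (useOverlap) {
      len <- min(len, max(width(copies)))   # must fit inside some copy
      wide <- which(width(copies) >= max(len, params$dupLenMin))
      if (length(wide)) {
        ci <- wide[sample.int(length(wide), 1)]
        off <- sample.int(width(copies)[ci] - len + 1L, 1) - 1L
        src <- GenomicRanges::shift(
          GRanges(seqnames(copies)[ci],
                  IRanges(start(copies)[ci], start(copies)[ci] + len - 1L)),
          off)
        parent <- ci
      } else useOverlap <- FALSE
    }
    if (!useOverlap) src <- placeFresh(len)
    tgt <- placeFresh(len)
    occupied <- suppressWarnings(c(occupied, tgt, src))
    ident <- identityOf(ev)
    addRecord(src, tgt, ident, TRUE, ev)
    if (!is.null(parent)) {
      # the source sits inside copy `parent`; the same sequence exists at
      # the locus `parent` was copied from -> secondary alignment
      off <- start(src) - start(copies)[parent]
      p <- copySrc[parent]
      pSub <- GRanges(seqnames(p), IRanges(start(p) + off,
                                           start(p) + off + len - 1L))
      addRecord(pSub, tgt, min(ident, identityOf(parent)), FALSE, ev)
    }
    copies <- suppressWarnings(c(copies, tgt))
    copySrc <- suppressWarnings(c(copySrc, src))
  }

  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chromA = character(0), startA = numeric(0),
               endA = numeric(0), chromB = character(0),
               startB = numeric(0), endB = numeric(0),
               identity = numeric(0), isPrimary = logical(0),
               event = integer(0))
  if (nrow(records)) records$id <- paste0("A", seq_len(nrow(records)))
  truth <- records[, c(if (nrow(records)) "id" else NULL,
                       "isPrimary", "event"), drop = FALSE]
  records <- records[, c("id", "chromA", "startA", "endA",
                         "chromB", "startB", "endB", "identity")[
                           if (nrow(records)) 1:8 else 2:8], drop = FALSE]

  # repeats: one planted family (enriched at breakpoints) + neutral ones
  repLen <- 300
  bgFamily <- function() {
    ch <- sample(chroms, params$nBackgroundRepeats, replace = TRUE)
    s <- vapply(ch, function(c2)
      sample.int(chromSizes[c2] - repLen, 1), numeric(1))
    GenomicRanges::sort(GRanges(ch, IRanges(s, s + repLen - 1)))
  }
  repeats <- list(Alu = bgFamily(), L1 = bgFamily(), DNA = bgFamily())
  dens <- params$nBackgroundRepeats / totalBp
  pPlant <- min(1, params$breakpointRepeatEnrichment * dens * 50)
  if (nrow(records) && pPlant > 0) {
    allCopies <- GRanges(c(records$chromA, records$chromB),
                         IRanges(c(records$startA, records$startB) + 1,
                                 c(records$endA, records$endB)))
    bpts <- data.frame(
      chrom = rep(as.character(seqnames(allCopies)), 2),
      pos = c(start(allCopies), end(allCopies)),
      left = rep(c(TRUE, FALSE), each = length(allCopies)))
    plant <- stats::runif(nrow(bpts)) < pPlant
    if (any(plant)) {
      b <- bpts[plant, , drop = FALSE]
      s <- ifelse(b$left, pmax(b$pos - repLen, 1), b$pos + 1)
      planted <- GRanges(b$chrom, IRanges(s, s + repLen - 1))
      repeats$Alu <- suppressWarnings(
        GenomicRanges::sort(c(repeats$Alu, planted)))
    }
  }

  # value tracks: a smooth random-walk replication-timing surrogate and a
  # track correlated with per-locus true duplication counts
  binBp <- 1e5
  timing <- suppressWarnings(do.call(c, lapply(chroms, function(ch) {
    nb <- ceiling(chromSizes[ch] / binBp)
    s <- (seq_len(nb) - 1) * binBp + 1
    gr <- GRanges(ch, IRanges(s, pmin(s + binBp - 1, chromSizes[ch])))
    mcols(gr)$score <- as.numeric(cumsum(stats::rnorm(nb, 0, 0.15)))
    gr
  })))
  assoc <- timing
  mcols(assoc)$score <- stats::rnorm(length(assoc))
  if (nrow(records)) {
    regs <- reduce(GRanges(c(records$chromA, records$chromB),
                           IRanges(c(records$startA, records$startB) + 1,
                                   c(records$endA, records$endB))))
    prim <- truth$isPrimary
    pr <- GRanges(c(records$chromA[prim], records$chromB[prim]),
                  IRanges(c(records$startA[prim], records$startB[prim]) + 1,
                          c(records$endA[prim], records$endB[prim])))
    cnt <- IRanges::countOverlaps(regs, pr)
    rho <- params$featureAssociationStrength
    z <- as.numeric(scale(cnt))
    if (any(!is.finite(z))) z <- rep(0, length(cnt))
    val <- rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(cnt))
    ov <- findOverlaps(assoc, regs)
    mcols(assoc)$score[S4Vectors::from(ov)] <- val[S4Vectors::to(ov)]
  }
  tracks <- list(timing = timing, assoc = assoc)

  cen <- GRanges(chroms, IRanges(chromSizes / 2 - 5e5, chromSizes / 2 + 5e5))
  tel <- suppressWarnings(
    c(GRanges(chroms, IRanges(1, 1e4)),
      GRanges(chroms, IRanges(chromSizes - 1e4 + 1, chromSizes))))

  bundle <- list(records = records, truth = truth, gaps = gaps,
                 repeats = repeats, tracks = tracks,
                 chromSizes = chromSizes, centromeres = cen,
                 telomeres = tel, params = params, files = NULL)
  if (!is.null(outDir)) bundle$files <- .writeFixture(bundle, outDir)
  bundle
}

# internal: write the bundle in the standard dialects
.writeFixture <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(outDir, x)
  files <- list()
  r <- bundle$records
  files$sd <- fp("sd_table.tsv")
  utils::write.table(r[, c("chromA", "startA", "endA", "chromB", "startB",
                           "endB", "identity")],
                     files$sd, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files$truth <- fp("truth.tsv")
  utils::write.table(cbind(id = r$id, bundle$truth[, c("isPrimary", "event")]),
                     files$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  writeBed <- function(gr, path) {
    utils::write.table(data.frame(as.character(seqnames(gr)),
                                  start(gr) - 1, end(gr)),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  files$gaps <- fp("gaps.bed")
  writeBed(bundle$gaps, files$gaps)
  for (fam in names(bundle$repeats)) {
    files[[paste0("repeat_", fam)]] <- fp(paste0("repeats_", fam, ".bed"))
    writeBed(bundle$repeats[[fam]], files[[paste0("repeat_", fam)]])
  }
  for (tr in names(bundle$tracks)) {
    g <- bundle$tracks[[tr]]
    files[[paste0("track_", tr)]] <- fp(paste0("track_", tr, ".bedgraph"))
    utils::write.table(data.frame(as.character(seqnames(g)), start(g) - 1,
                                  end(g), mcols(g)$score),
                       files[[paste0("track_", tr)]], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  files$chromSizes <- fp("chrom_sizes.tsv")
  utils::write.table(data.frame(names(bundle$chromSizes),
                                unname(bundle$chromSizes)),
                     files$chromSizes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files$cenTel <- fp("cen_tel.tsv")
  ct <- rbind(
    data.frame(chrom = as.character(seqnames(bundle$centromeres)),
               start = start(bundle$centromeres) - 1,
               end = end(bundle$centromeres), type = "centromere"),
    data.frame(chrom = as.character(seqnames(bundle$telomeres)),
               start = start(bundle$telomeres) - 1,
               end = end(bundle$telomeres), type = "telomere"))
  utils::write.table(ct, files$cenTel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files
}

#' End-to-end round trip of a fixture through the pipeline
#'
#' Parses the emitted SD table back in, builds regions and the network,
#' flags suspicious edges against the fixture's gaps, reconstructs the
#' spanning forest, and scores it against the fixture truth: an edge is a
#' true primary when at least one primary alignment backs it, and a
#' region's true duplication count is the number of primary alignments
#' touching it.
#'
#' @param bundle a [generateFixture()] bundle.
#' @param seed forest tie-break seed.
#' @return list: `edgesMatch` (%), `r2`, `net`, `forest`, `trueCounts`.
#' @export
roundtripCheck <- function(bundle, seed = 1L) {
  rec <- bundle$records
  if (!nrow(rec)) stop("empty fixture bundle")
  reg <- buildDuplicatedRegions(rec)
  net <- buildNetwork(reg, rec)
  net <- flagSuspiciousEdges(net, bundle$gaps)
  net <- assignWeights(net)
  fo <- minimumSpanningForest(net, seed = seed)

  aln <- alignments(net)
  prim <- bundle$truth$isPrimary[match(aln$id, bundle$truth$id)]
  ekey <- paste(pmin(aln$nodeA, aln$nodeB), pmax(aln$nodeA, aln$nodeB))
  primaryEdge <- tapply(prim, ekey, any)
  fkey <- paste(pmin(fo@edges$from, fo@edges$to),
                pmax(fo@edges$from, fo@edges$to))
  match_ <- 100 * mean(as.logical(primaryEdge[fkey]))

  pIv <- GRanges(c(rec$chromA[prim], rec$chromB[prim]),
                 IRanges(c(rec$startA[prim], rec$startB[prim]) + 1,
                         c(rec$endA[prim], rec$endB[prim])))
  trueCounts <- IRanges::countOverlaps(reg, pIv)
  r2 <- if (stats::sd(trueCounts) > 0)
    varianceExplained(duplicationCounts(fo), trueCounts) else NA_real_
  list(edgesMatch = match_, r2 = r2, net = net, forest = fo,
       trueCounts = trueCounts)
}
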