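# Duplication signatures: windowed feature matrix construction,
# KL-divergence NMF with multiplicative updates, rank selection (Fogel
# & Young volume + signature stability), nonnegative regression
# assignment of regions to signatures, and chromosome-zone labels.

#' Build the windows x features matrix for signature analysis
#'
#' The genome is tiled with nonoverlapping `windowBp` windows; every
#' duplicated region contributes its feature vector to *each* window it
#' overlaps, and window rows are the sums of their contributing regions.
#' Before summation, the features named in `binCols` (by default: region
#' length, G/C content inside and at flanks, and sequence identity) are
#' replaced by a pair of below-mean/above-mean indicator columns, which
#' keeps bimodal features from being washed out by averaging.  Afterwards
#' every column is min-max scaled to [0, 1] so no feature dominates the
#' factorization by magnitude.  All-zero windows are dropped with a note.
#'
#' @param regions `GRanges` of duplicated regions.
#' @param features `data.frame` of per-region features (rows parallel to
#'   `regions`).
#' @param windowBp window width in bp (default 10 Mb).
#' @param chromSizes named vector of chromosome lengths.
#' @param binCols features to mean-bin into indicator pairs (defaults to
#'   the intersection of `c("length", "gc_inside", "gc_flank",
#'   "identity")` with the available columns).
#' @return a list: `A` (the scaled matrix), `windows` (`GRanges` of kept
#'   windows), `encoder` (binning means and column ranges, needed by
#'   [assignSignatures()] to encode single regions identically).
#' @export
buildWindowMatrix <- function(regions, features, windowBp = 1e7, chromSizes,
                              binCols = intersect(
                                c("length", "gc_inside", "gc_flank",
                                  "identity"),
                                colnames(features))) {
  if (windowBp <= 0) stop("windowBp must be positive")
  if (length(regions) != nrow(features))
    stop("features must have one row per region")
  enc <- list(binCols = binCols,
              binMeans = vapply(binCols, function(cn)
                mean(features[[cn]]), numeric(1)))
  encoded <- .encodeRegionFeatures(features, enc)
  tiles <- unlist(GenomicRanges::tileGenome(chromSizes,
                                            tilewidth = windowBp))
  ov <- findOverlaps(regions, tiles)
  A <- matrix(0, length(tiles), ncol(encoded),
              dimnames = list(NULL, colnames(encoded)))
  for (h in seq_along(ov)) {
    r <- S4Vectors::from(ov)[h]; wdx <- S4Vectors::to(ov)[h]
    A[wdx, ] <- A[wdx, ] + as.numeric(encoded[r, ])
  }
  nz <- rowSums(A) > 0
  if (any(!nz))
    message(sum(!nz), " all-zero window(s) dropped")
  A <- A[nz, , drop = FALSE]
  cmin <- apply(A, 2, min)
  cmax <- apply(A, 2, max)
  scale <- ifelse(cmax > cmin, cmax - cmin, 1)
  A <- sweep(sweep(A, 2, cmin), 2, scale, "/")
  enc$colMin <- cmin
  enc$colMax <- cmax
  enc$featureNames <- colnames(A)
  list(A = A, windows = tiles[nz], encoder = enc)
}

# internal: expand binCols into below/above-mean indicators
.encodeRegionFeatures <- function(features, enc) {
  out <- features[, setdiff(colnames(features), enc$binCols), drop = FALSE]
  for (cn in enc$binCols) {
    m <- enc$binMeans[[cn]]
    out[[paste0(cn, "_below")]] <- as.numeric(features[[cn]] <= m)
    out[[paste0(cn, "_above")]] <- as.numeric(features[[cn]] > m)
  }
  as.matrix(out)
}

# internal: KL divergence D(A || WH), with the convention 0*log(0/x) = 0
.klLoss <- function(A, WH) {
  eps <- .Machine$double.eps
  pos <- A > 0
  sum(A[pos] * log(A[pos] / pmax(WH[pos], eps))) - sum(A) + sum(WH)
}

#' Nonnegative matrix factorization with Kullback-Leibler loss
#'
#' Factorizes a nonnegative matrix `A` (n x f) into `W` (n x k) times `H`
#' (k x f) by the multiplicative update rules for the generalized KL
#' divergence.  The loss is nonincreasing along the iteration; updates
#' stop at `maxIter` or when the relative loss change falls below `tol`.
#' Initialization is seeded uniform random in (0, 1], scaled by
#' `mean(A)/k`.
#'
#' @param A nonnegative numeric matrix.
#' @param k rank (>= 1).
#' @param maxIter iteration cap (default 500).
#' @param tol relative loss-change stopping tolerance (default 1e-6).
#' @param seed integer seed for the initialization.
#' @return a [SignatureModel-class] (its `encoder` slot empty; see
#'   [buildWindowMatrix()] for the full pipeline).
#' @export
nmfKl <- function(A, k, maxIter = 500, tol = 1e-6, seed = 1L) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("A must be nonnegative")
  if (k < 1) stop("k must be at least 1")
  n <- nrow(A); f <- ncol(A)
  set.seed(seed)
  scl <- max(mean(A), .Machine$double.eps) / k
  W <- matrix(stats::runif(n * k, min = .Machine$double.eps), n, k) * scl
  H <- matrix(stats::runif(k * f, min = .Machine$double.eps), k, f) * scl
  eps <- .Machine$double.eps
  loss <- numeric(0)
  prev <- Inf
  for (it in seq_len(maxIter)) {
    WH <- W %*% H
    H <- H * (t(W) %*% (A / pmax(WH, eps))) / pmax(colSums(W), eps)
    WH <- W %*% H
    W <- W * ((A / pmax(WH, eps)) %*% t(H)) / pmax(rep(1, n) %o% rowSums(H), eps)
    cur <- .klLoss(A, W %*% H)
    loss <- c(loss, cur)
    if (is.finite(prev) && prev > 0 &&
        abs(prev - cur) / max(prev, eps) < tol) break
    prev <- cur
  }
  new("SignatureModel", A = A, W = W, H = H, k = as.integer(k),
      lossTrace = loss, encoder = list())
}

#' @rdname accessors
#' @export
setMethod("signatures", "SignatureModel", function(x) x@H)

#' @rdname accessors
#' @export
setMethod("signatureWeights", "SignatureModel", function(x) x@W)

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel: rank", object@k, "factorization of a",
      nrow(object@A), "x", ncol(object@A), "matrix\n")
  cat("  final KL loss:", signif(utils::tail(object@lossTrace, 1), 6),
      "after", length(object@lossTrace), "iterations\n")
})

# internal: cosine similarity matrix between rows of two matrices
.cosineRows <- function(X, Y) {
  nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
  (X %*% t(Y)) / pmax(nx %o% ny, .Machine$double.eps)
}

# internal: mean cosine of greedily matched row pairs (one-to-one)
.matchedCosine <- function(X, Y) {
  S <- .cosineRows(X, Y)
  total <- 0
  for (step in seq_len(nrow(S))) {
    best <- which(S == max(S), arr.ind = TRUE)[1, ]
    total <- total + S[best[1], best[2]]
    S[best[1], ] <- -Inf
    S[, best[2]] <- -Inf
  }
  total / nrow(X)
}

#' Choose the number of signatures
#'
#' Runs `nRestarts` seeded factorizations per candidate rank and reports
#' two diagnostics: the Fogel-Young volume (FYV) score — the determinant
#' of the correlation matrix of the signature rows of the best-loss run,
#' near 1 for well-spread signatures and near 0 when two signatures are
#' nearly collinear — and the stability score — the mean cosine
#' similarity of optimally matched signature pairs across restarts.  Both
#' are reported per k; the choice is left to the user (the two
#' diagnostics can and do disagree).
#'
#' @param A nonnegative matrix (windows x features).
#' @param kRange candidate ranks (each >= 2).
#' @param nRestarts restarts per rank (>= 2 for stability; default 50).
#' @param seed integer seed.
#' @param maxIter per-run iteration cap.
#' @return `data.frame`: `k`, `fyv`, `stability`, plus an attribute
#'   `recommendation` (the k maximizing stability, ties to smaller k).
#' @export
selectK <- function(A, kRange = 2:6, nRestarts = 50, seed = 1L,
                    maxIter = 300) {
  if (any(kRange < 2)) stop("kRange must be >= 2")
  if (nRestarts < 2) stop("stability needs at least 2 restarts")
  out <- data.frame(k = kRange, fyv = NA_real_, stability = NA_real_)
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    runs <- vector("list", nRestarts)
    losses <- numeric(nRestarts)
    for (r in seq_len(nRestarts)) {
      m <- nmfKl(A, k, maxIter = maxIter, seed = seed + 1000L * i + r)
      H <- m@H
      zero <- rowSums(H) == 0
      if (any(zero)) {
        warning("restart ", r, " at k=", k, " produced a zero signature; ",
                "excluded")
        runs[r] <- list(NULL)
        losses[r] <- Inf
        next
      }
      runs[[r]] <- H / rowSums(H)
      losses[r] <- utils::tail(m@lossTrace, 1)
    }
    ok <- !vapply(runs, is.null, logical(1))
    if (sum(ok) < 2) next
    bestH <- runs[[which.min(losses)]]
    R <- suppressWarnings(stats::cor(t(bestH)))
    R[!is.finite(R)] <- 1
    out$fyv[i] <- det(R)
    idx <- which(ok)
    pairs <- utils::combn(idx, 2)
    out$stability[i] <- mean(apply(pairs, 2, function(pq)
      .matchedCosine(runs[[pq[1]]], runs[[pq[2]]])))
  }
  best <- out$k[which.max(out$stability)]
  attr(out, "recommendation") <- best
  out
}

#' Assign duplicated regions to signatures by nonnegative regression
#'
#' Each region's encoded feature vector (same binning and min-max scale
#' as the windowed matrix) is regressed on the signature rows with
#' nonnegative least squares; the signature with the largest weight is
#' responsible for the region.  All-zero vectors and exact ties are
#' unassigned (`NA`), reported in the `tie` column.
#'
#' @param features per-region feature `data.frame` (same columns the
#'   window matrix was built from).
#' @param H signature matrix (k x features).
#' @param encoder the `encoder` from [buildWindowMatrix()].
#' @return list: `assignment` (`data.frame`: `signature` (integer or NA),
#'   `tie`), `weights` (regions x k matrix).
#' @export
assignSignatures <- function(features, H, encoder) {
  enc <- .encodeRegionFeatures(features, encoder)
  enc <- enc[, encoder$featureNames, drop = FALSE]
  scale <- ifelse(encoder$colMax > encoder$colMin,
                  encoder$colMax - encoder$colMin, 1)
  X <- sweep(sweep(enc, 2, encoder$colMin), 2, scale, "/")
  C <- t(H)
  k <- nrow(H)
  n <- nrow(X)
  Wt <- matrix(0, n, k)
  sig <- rep(NA_integer_, n)
  tie <- rep(FALSE, n)
  for (i in seq_len(n)) {
    y <- as.numeric(X[i, ])
    if (all(y == 0)) next
    w <- pracma::lsqnonneg(C, y)$x
    Wt[i, ] <- w
    mx <- max(w)
    if (mx <= 0) next
    top <- which(w == mx)
    if (length(top) > 1L) { tie[i] <- TRUE; next }
    sig[i] <- top
  }
  list(assignment = data.frame(signature = sig, tie = tie), weights = Wt)
}

#' Chromosome-zone label of a duplicated region
#'
#' Labels regions within `dBp` (5 Mb) of a telomere as subtelomeric and
#' within `dBp` of a centromere as pericentromeric (pericentromeric wins
#' when both apply); everything else is interstitial.  Distances are from
#' the region's nearest edge.
#'
#' @param regions `GRanges`.
#' @param centromeres `GRanges` of centromere intervals (one per
#'   chromosome).
#' @param telomeres `GRanges` of telomere intervals (typically two per
#'   chromosome).
#' @param dBp distance threshold (default 5e6).
#' @return character vector: `"subtelomeric"`, `"pericentromeric"` or
#'   `"interstitial"`.
#' @export
chromosomeZone <- function(regions, centromeres, telomeres, dBp = 5e6) {
  chr <- as.character(seqnames(regions))
  missing <- setdiff(chr, union(as.character(seqnames(centromeres)),
                                as.character(seqnames(telomeres))))
  if (length(missing))
    stop("no centromere/telomere coordinates for: ",
         paste(unique(missing), collapse = ", "))
  dCen <- suppressWarnings(
    GenomicRanges::distanceToNearest(regions, centromeres))
  dTel <- suppressWarnings(
    GenomicRanges::distanceToNearest(regions, telomeres))
  dc <- rep(Inf, length(regions))
  dt <- rep(Inf, length(regions))
  dc[S4Vectors::from(dCen)] <- mcols(dCen)$distance
  dt[S4Vectors::from(dTel)] <- mcols(dTel)$distance
  ifelse(dc <= dBp, "pericentromeric",
         ifelse(dt <= dBp, "subtelomeric", "interstitial"))
}
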