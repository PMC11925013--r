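# Genomic feature extraction for duplicated regions, shuffled-background
# comparisons, breakpoint repeat profiles, and association tests
# (permutation-calibrated random forest, partial Spearman correlation).

#' Define a genomic feature track
#'
#' A feature is measured either inside a duplicated region (between its
#' breakpoints) or on its two 50-bp flanks (summed for counts, averaged
#' for means).  Kinds: `count` (number of overlapping intervals), `mean`
#' (coverage-weighted mean of a value track), `fraction` (fraction of bp
#' covered by the track), `span` (max minus min of the value track over
#' the interval — used as the replication-pausing proxy on replication
#' timing).
#'
#' @param name feature name.
#' @param kind one of `"count"`, `"mean"`, `"fraction"`, `"span"`.
#' @param position `"inside"` or `"flank"`.
#' @param track a `GRanges`; for `mean`/`span` kinds it must carry a
#'   numeric `score` column.
#' @return a `featureTrack` list.
#' @export
featureTrack <- function(name, kind = c("count", "mean", "fraction", "span"),
                         position = c("inside", "flank"), track) {
  kind <- match.arg(kind)
  position <- match.arg(position)
  if (kind %in% c("mean", "span") && is.null(mcols(track)$score))
    stop("mean/span tracks need a numeric `score` column: ", name)
  structure(list(name = name, kind = kind, position = position,
                 track = track), class = "featureTrack")
}

# internal: measure one track kind over a set of query intervals, one
# value per query
.measureTrack <- function(query, kind, track) {
  n <- length(query)
  out <- numeric(n)
  ov <- suppressWarnings(findOverlaps(query, track))
  if (!length(ov)) {
    if (kind == "mean") out[] <- NA_real_
    return(out)
  }
  qi <- S4Vectors::from(ov); ti <- S4Vectors::to(ov)
  if (kind == "count") {
    t <- table(qi)
    out[as.integer(names(t))] <- as.integer(t)
  } else if (kind == "fraction") {
    w <- width(pintersect(query[qi], track[ti]))
    cov <- vapply(split(seq_along(qi), qi), function(i) {
      # merge overlapping track pieces so covered bp are not double-counted
      sum(width(reduce(pintersect(query[qi[i]], track[ti[i]]))))
    }, numeric(1))
    out[as.integer(names(cov))] <- cov / width(query)[as.integer(names(cov))]
  } else if (kind == "mean") {
    out[] <- NA_real_
    w <- width(pintersect(query[qi], track[ti]))
    v <- mcols(track)$score[ti]
    num <- tapply(w * v, qi, sum)
    den <- tapply(w, qi, sum)
    out[as.integer(names(num))] <- num / den
  } else if (kind == "span") {
    v <- mcols(track)$score[ti]
    mx <- tapply(v, qi, max)
    mn <- tapply(v, qi, min)
    out[as.integer(names(mx))] <- mx - mn
  }
  out
}

#' Extract a feature matrix for duplicated regions
#'
#' Inside features are measured on the region itself; flank features on
#' the two `flankBp`-wide intervals padding it (the two flanks are not
#' distinguished: counts/fractions are summed, means averaged with
#' coverage weighting, spans taken over both flanks jointly).  Flanks
#' running past a chromosome end are truncated and flagged.  Regions with
#' no overlapping value-track interval get the chromosome mean of the
#' track for `mean` kinds (0 for `span`) plus a missingness flag column.
#'
#' @param regions `GRanges` of duplicated regions.
#' @param tracks list of [featureTrack()] definitions.
#' @param flankBp flank width (default 50).
#' @param chromSizes named vector of chromosome lengths (for flank
#'   truncation); optional.
#' @return `data.frame`, rows = regions, columns = features (named as the
#'   tracks, flank features suffixed `_flank` if a name collides), plus
#'   `<name>_missing` flags where imputation occurred and a
#'   `flank_truncated` flag.
#' @export
extractFeatures <- function(regions, tracks, flankBp = 50,
                            chromSizes = NULL) {
  n <- length(regions)
  out <- data.frame(row.names = seq_len(n))
  chr <- as.character(seqnames(regions))
  left <- GRanges(chr, IRanges(pmax(start(regions) - flankBp, 1),
                               pmax(start(regions) - 1, 0)))
  rightEnd <- end(regions) + flankBp
  truncated <- start(regions) - flankBp < 1
  if (!is.null(chromSizes)) {
    lim <- unname(chromSizes[chr])
    truncated <- truncated | rightEnd > lim
    rightEnd <- pmin(rightEnd, lim)
  }
  right <- GRanges(chr, IRanges(pmin(end(regions) + 1, rightEnd + 1),
                                rightEnd))
  for (tr in tracks) {
    if (tr$position == "inside") {
      v <- .measureTrack(regions, tr$kind, tr$track)
    } else {
      vl <- .measureTrack(left, tr$kind, tr$track)
      vr <- .measureTrack(right, tr$kind, tr$track)
      v <- switch(tr$kind,
        count = vl + vr,
        fraction = (vl * width(left) + vr * width(right)) /
          pmax(width(left) + width(right), 1),
        mean = ifelse(is.na(vl), vr, ifelse(is.na(vr), vl, (vl + vr) / 2)),
        span = pmax(vl, vr))
    }
    if (tr$kind == "mean" && anyNA(v)) {
      miss <- is.na(v)
      chromMean <- tapply(mcols(tr$track)$score,
                          as.character(seqnames(tr$track)), mean)
      fill <- chromMean[chr[miss]]
      fill[is.na(fill)] <- mean(mcols(tr$track)$score)
      v[miss] <- fill
      out[[paste0(tr$name, "_missing")]] <- as.integer(miss)
    }
    out[[tr$name]] <- v
  }
  out$flank_truncated <- as.integer(truncated)
  out
}

#' Network-derived features of duplicated regions
#'
#' The per-node columns used alongside the genomic tracks: region length,
#' degree, fraction of intrachromosomal edges among a node's edges,
#' self-loop count, multi-alignment (double) edge count, and the maximal
#' edge identity at the node.
#'
#' @param net an `SDNetwork`.
#' @return `data.frame`, one row per node.
#' @export
networkFeatures <- function(net) {
  e <- edgeTable(net)
  n <- nNodes(net)
  deg <- tabulate(c(e$nodeA, e$nodeB), n)
  intra <- tabulate(c(e$nodeA[e$intrachromosomal],
                      e$nodeB[e$intrachromosomal]), n)
  ident <- rep(NA_real_, n)
  for (i in seq_len(nrow(e))) {
    a <- e$nodeA[i]; b <- e$nodeB[i]; mi <- e$maxIdentity[i]
    if (is.na(ident[a]) || mi > ident[a]) ident[a] <- mi
    if (is.na(ident[b]) || mi > ident[b]) ident[b] <- mi
  }
  data.frame(
    length = width(regions(net)),
    degree = deg,
    intra_fraction = ifelse(deg > 0, intra / deg, 0),
    self_loops = selfLoops(net),
    double_edges = doubleEdges(net),
    identity = ifelse(is.na(ident), 1, ident)
  )
}

# internal: place length-preserving random intervals on the autosomes,
# avoiding assembly gaps
.shuffleIntervals <- function(widths, chromSizes, gaps) {
  chroms <- names(chromSizes)
  placed <- vector("list", length(widths))
  probs <- chromSizes / sum(chromSizes)
  for (i in seq_along(widths)) {
    w <- widths[i]
    ok <- FALSE
    for (try in 1:200) {
      chr <- sample(chroms, 1, prob = probs)
      if (chromSizes[chr] < w) next
      s <- sample.int(chromSizes[chr] - w + 1, 1)
      cand <- GRanges(chr, IRanges(s, s + w - 1))
      if (length(gaps) == 0 ||
          !suppressWarnings(IRanges::overlapsAny(cand, gaps))) {
        placed[[i]] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place an interval of width ", w,
           " outside assembly gaps (region ", i, ")")
  }
  suppressWarnings(do.call(c, placed))
}

#' Compare duplicated regions to a shuffled genomic background
#'
#' For each feature, the observed mean over the duplicated regions is
#' tested against the distribution of means obtained from `nShuffles`
#' length-preserving random placements on the autosomes (excluding
#' assembly gaps).  The background is summarized by the shuffle means'
#' arithmetic mean and sample variance (a normal approximation); the
#' two-sided p-value is Bonferroni-adjusted across features.
#'
#' @param regions `GRanges` of duplicated regions.
#' @param tracks list of [featureTrack()] definitions.
#' @param chromSizes named vector of chromosome lengths.
#' @param gaps `GRanges` of assembly gaps.
#' @param nShuffles number of shuffles (>= 2; default 100).
#' @param seed integer seed.
#' @param flankBp flank width passed to extraction.
#' @return `data.frame`: `feature`, `observed`, `background_mean`,
#'   `background_sd`, `z`, `p`, `p_bonferroni`.
#' @export
backgroundComparison <- function(regions, tracks, chromSizes,
                                 gaps = GRanges(), nShuffles = 100,
                                 seed = 1L, flankBp = 50) {
  if (nShuffles < 2) stop("nShuffles must be at least 2 (variance undefined)")
  set.seed(seed)
  obs <- extractFeatures(regions, tracks, flankBp, chromSizes)
  featNames <- vapply(tracks, `[[`, character(1), "name")
  obsMean <- vapply(featNames, function(f) mean(obs[[f]]), numeric(1))
  bg <- matrix(NA_real_, nShuffles, length(featNames),
               dimnames = list(NULL, featNames))
  for (s in seq_len(nShuffles)) {
    shuf <- .shuffleIntervals(width(regions), chromSizes, gaps)
    sf <- extractFeatures(shuf, tracks, flankBp, chromSizes)
    bg[s, ] <- vapply(featNames, function(f) mean(sf[[f]]), numeric(1))
  }
  mu <- colMeans(bg)
  sdv <- apply(bg, 2, stats::sd)
  z <- ifelse(sdv > 0, (obsMean - mu) / sdv, 0)
  p <- ifelse(sdv > 0, 2 * stats::pnorm(-abs(z)), 1)
  data.frame(
    feature = featNames,
    observed = unname(obsMean),
    background_mean = unname(mu),
    background_sd = unname(sdv),
    z = unname(z),
    p = unname(p),
    p_bonferroni = pmin(unname(p) * length(featNames), 1),
    row.names = NULL
  )
}

# internal: window GRanges for one offset (bp from the breakpoint; >= 0
# outside, < 0 inside), for all regions, both breakpoints
.offsetWindows <- function(regions, offset, winBp) {
  chr <- as.character(seqnames(regions))
  if (offset >= 0) {
    # outside: left breakpoint extends leftward, right breakpoint rightward
    ls <- start(regions) - offset - winBp
    le <- start(regions) - offset - 1
    rs <- end(regions) + offset + 1
    re <- end(regions) + offset + winBp
  } else {
    # inside: [-50;-1] abuts the breakpoint from within
    d <- -offset  # 50, 100, ...
    ls <- start(regions) + d - winBp
    le <- start(regions) + d - 1
    rs <- end(regions) - d + 1
    re <- end(regions) - d + winBp
    # windows that do not fit inside the region are dropped
    keep <- width(regions) >= d
    ls[!keep] <- NA
    rs[!keep] <- NA
  }
  w <- data.frame(chr = c(chr, chr), s = c(ls, rs), e = c(le, re))
  w <- w[!is.na(w$s) & w$s >= 1, , drop = FALSE]
  if (!nrow(w)) return(GRanges())
  GRanges(w$chr, IRanges(w$s, w$e))
}

#' Repeat frequency profile around duplication breakpoints
#'
#' Slides nonoverlapping `winBp`-wide windows symmetrically from both
#' breakpoints of every region: `nInside` window steps into the region
#' (offsets -50..-1 down to -250..-201 for the defaults) and `nOutside`
#' steps away from it (0..49 up to 1,450..1,499).  The frequency at an
#' offset is the number of repeats overlapping (by >= 1 bp) any window at
#' that offset divided by the number of windows placed there.  A
#' background band is produced by applying the same scheme to `nRandom`
#' random length-preserving placements of the regions.
#'
#' @param regions `GRanges` of duplicated regions.
#' @param repeatTrack `GRanges` of repeat intervals.
#' @param winBp window width (50).
#' @param nInside,nOutside window steps inside/outside (5 / 30).
#' @param nRandom random placements for the background (10).
#' @param chromSizes named vector of chromosome lengths (needed for the
#'   background placements).
#' @param gaps `GRanges` excluded from random placement.
#' @param seed integer seed.
#' @return list with `profile` (`data.frame`: `offset` — bp of the window
#'   start relative to the breakpoint, negative inside — `frequency`,
#'   `n_windows`) and `background` (matrix, `nRandom` x offsets).
#' @export
breakpointWindowProfile <- function(regions, repeatTrack, winBp = 50,
                                    nInside = 5, nOutside = 30, nRandom = 10,
                                    chromSizes = NULL, gaps = GRanges(),
                                    seed = 1L) {
  offsets <- c(-(nInside:1) * winBp, (0:(nOutside - 1)) * winBp)
  profileOf <- function(reg) {
    vapply(offsets, function(o) {
      w <- .offsetWindows(reg, o, winBp)
      if (!length(w)) return(c(0, 0))
      c(sum(suppressWarnings(IRanges::countOverlaps(w, repeatTrack))),
        length(w))
    }, numeric(2))
  }
  obs <- profileOf(regions)
  freq <- ifelse(obs[2, ] > 0, obs[1, ] / obs[2, ], 0)
  bg <- NULL
  if (nRandom > 0) {
    if (is.null(chromSizes))
      stop("chromSizes needed for random background placements")
    set.seed(seed)
    bg <- matrix(NA_real_, nRandom, length(offsets))
    for (r in seq_len(nRandom)) {
      shuf <- .shuffleIntervals(width(regions), chromSizes, gaps)
      o <- profileOf(shuf)
      bg[r, ] <- ifelse(o[2, ] > 0, o[1, ] / o[2, ], 0)
    }
    colnames(bg) <- offsets
  }
  list(
    profile = data.frame(offset = offsets, frequency = freq,
                         n_windows = obs[2, ]),
    background = bg
  )
}

#' Random-forest feature importance with permutation-calibrated p-values
#'
#' Fits a random forest predicting the per-region duplication count from
#' the feature matrix and records each feature's impurity importance.  The
#' response is then permuted `nPerm` times and the forest refit; the
#' empirical p-value of a feature is the fraction of permutations in which
#' its importance reached at least the observed value, which calibrates
#' away the biases of raw impurity importances.  Model quality is reported
#' as cross-validated R-squared (`1 - SSE/SST` over held-out folds).
#'
#' @param X `data.frame`/matrix of features (rows = regions).
#' @param y numeric response (duplication counts), not constant.
#' @param nTrees trees per forest (default 500).
#' @param nPerm response permutations (>= 1; default 1000).
#' @param cvFolds cross-validation folds (default 5).
#' @param seed integer seed.
#' @return list: `importance` (`data.frame`: `feature`, `importance`,
#'   `p_empirical`), `r2_cv`.
#' @export
rfImportance <- function(X, y, nTrees = 500, nPerm = 1000, cvFolds = 5,
                         seed = 1L) {
  if (nPerm < 1) stop("nPerm must be at least 1")
  if (stats::sd(y) == 0) stop("constant response")
  X <- as.data.frame(X)
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = y, ntree = nTrees,
                                    importance = FALSE)
  obs <- randomForest::importance(fit, type = 2)[, 1]
  perm <- matrix(NA_real_, nPerm, ncol(X))
  for (i in seq_len(nPerm)) {
    pf <- randomForest::randomForest(x = X, y = sample(y), ntree = nTrees,
                                     importance = FALSE)
    perm[i, ] <- randomForest::importance(pf, type = 2)[, 1]
  }
  pEmp <- vapply(seq_len(ncol(X)), function(j)
    mean(perm[, j] >= obs[j]), numeric(1))

  folds <- sample(rep_len(seq_len(cvFolds), nrow(X)))
  pred <- numeric(nrow(X))
  for (k in seq_len(cvFolds)) {
    hold <- folds == k
    f <- randomForest::randomForest(x = X[!hold, , drop = FALSE],
                                    y = y[!hold], ntree = nTrees)
    pred[hold] <- stats::predict(f, X[hold, , drop = FALSE])
  }
  r2cv <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)

  list(
    importance = data.frame(feature = colnames(X),
                            importance = unname(obs),
                            p_empirical = pEmp,
                            row.names = NULL),
    r2_cv = r2cv
  )
}

#' Partial Spearman correlation of each feature with the response
#'
#' All columns are rank-transformed; each feature's partial correlation
#' with the response, controlling for every other feature, is computed
#' both by residualization (regressing feature and response on the
#' controls and correlating the residuals) and through the precision
#' matrix of the joint correlation matrix — the two routes must agree,
#' which guards against numerical trouble.  Confidence intervals use the
#' Fisher z transform with variance `1/(n - g - 3)` where `g` is the
#' number of controlled variables; p-values come from the t distribution
#' with `n - g - 2` degrees of freedom.
#'
#' @param X `data.frame`/matrix of features.
#' @param y numeric response.
#' @param conf confidence level (default 0.95).
#' @return `data.frame`: `feature`, `rho_partial`, `rho_simple`,
#'   `ci_lo`, `ci_hi` (for the partial coefficient), `p`.
#' @export
partialSpearman <- function(X, y, conf = 0.95) {
  X <- as.data.frame(X)
  n <- nrow(X)
  g <- ncol(X) - 1L
  if (n <= ncol(X) + 2) stop("need more rows than features + 2")
  Xr <- vapply(X, rank, numeric(n))
  yr <- rank(y)
  keep <- apply(Xr, 2, stats::sd) > 0
  if (!all(keep))
    stop("constant feature(s): ",
         paste(colnames(Xr)[!keep], collapse = ", "))
  M <- cbind(Xr, .response = yr)
  R <- stats::cor(M)
  P <- if (ncol(Xr) > 1L) {
    tryCatch(solve(R), error = function(e)
      stop("collinear feature block (rank-deficient correlation matrix); ",
           "inspect features: ", paste(colnames(Xr), collapse = ", ")))
  } else NULL   # nothing to control for: partial = simple
  yIdx <- ncol(M)
  out <- data.frame(feature = colnames(Xr),
                    rho_partial = NA_real_, rho_simple = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                    row.names = NULL)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  for (j in seq_len(ncol(Xr))) {
    # two routes that must agree: the precision-matrix identity and
    # residualization on the controls
    ctrl <- Xr[, -j, drop = FALSE]
    if (ncol(ctrl)) {
      rx <- stats::lm.fit(cbind(1, ctrl), Xr[, j])$residuals
      ry <- stats::lm.fit(cbind(1, ctrl), yr)$residuals
      rhoRes <- stats::cor(rx, ry)
      rhoP <- -P[j, yIdx] / sqrt(P[j, j] * P[yIdx, yIdx])
      if (abs(rhoP - rhoRes) > 1e-6)
        stop("partial-correlation routes disagree for ", colnames(Xr)[j],
             " (", rhoP, " vs ", rhoRes, ")")
    } else rhoP <- rhoRes <- stats::cor(Xr[, j], yr)
    z <- atanh(min(max(rhoP, -1 + 1e-12), 1 - 1e-12))
    sdz <- 1 / sqrt(n - g - 3)
    tstat <- rhoP * sqrt((n - g - 2) / (1 - rhoP^2))
    out$rho_partial[j] <- rhoP
    out$rho_simple[j] <- stats::cor(Xr[, j], yr)
    out$ci_lo[j] <- tanh(z - zq * sdz)
    out$ci_hi[j] <- tanh(z + zq * sdz)
    out$p[j] <- 2 * stats::pt(-abs(tstat), df = n - g - 2)
  }
  out
}
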