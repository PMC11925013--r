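library(GenomicRanges)

test_that("count, fraction, mean and span kinds measure as defined", {
  reg <- GRanges("chr1", IRanges(1001, 2000))
  reps <- GRanges("chr1", IRanges(c(1100, 1500, 1900, 5000),
                                  c(1150, 1550, 1950, 5050)))
  vals <- GRanges("chr1", IRanges(c(1001, 1401, 1801), c(1400, 1800, 2000)))
  mcols(vals)$score <- c(0.2, 0.9, 0.4)
  fm <- extractFeatures(reg, list(
    featureTrack("reps", "count", "inside", reps),
    featureTrack("cov", "fraction", "inside", reps),
    featureTrack("timing", "mean", "inside", vals),
    featureTrack("pausing", "span", "inside", vals)))
  expect_equal(fm$reps, 3)
  expect_equal(fm$cov, (51 * 3) / 1000)
  expect_equal(fm$timing, (400 * 0.2 + 400 * 0.9 + 200 * 0.4) / 1000)
  expect_equal(fm$pausing, 0.9 - 0.2)   # max - min over the interval
})

test_that("flank features sum counts and average means across both flanks", {
  reg <- GRanges("chr1", IRanges(1001, 2000))
  reps <- GRanges("chr1", IRanges(c(960, 2010, 1500), c(1000, 2049, 1550)))
  vals <- GRanges("chr1", IRanges(c(951, 2001), c(1000, 2050)))
  mcols(vals)$score <- c(1, 3)
  fm <- extractFeatures(reg, list(
    featureTrack("reps", "count", "flank", reps),
    featureTrack("timing", "mean", "flank", vals)))
  expect_equal(fm$reps, 2)            # one repeat per flank; inside ignored
  expect_equal(fm$timing, 2)          # (1 + 3) / 2
  expect_equal(fm$flank_truncated, 0)
})

test_that("flanks at chromosome boundaries are truncated and flagged", {
  reg <- GRanges("chr1", IRanges(c(21, 9951), c(120, 10000)))
  fm <- extractFeatures(reg, list(
    featureTrack("reps", "count", "flank",
                 GRanges("chr1", IRanges(1, 10)))),
    chromSizes = c(chr1 = 10000))
  expect_equal(fm$flank_truncated, c(1, 1))
  expect_equal(fm$reps[1], 1)   # left flank [1,20] catches the repeat
})

test_that("regions without value-track coverage are imputed and flagged", {
  reg <- GRanges("chr1", IRanges(c(101, 5001), c(200, 5100)))
  vals <- GRanges("chr1", IRanges(101, 300))
  mcols(vals)$score <- 2
  fm <- extractFeatures(reg, list(
    featureTrack("timing", "mean", "inside", vals)))
  expect_equal(fm$timing, c(2, 2))   # second imputed with the chrom mean
  expect_equal(fm$timing_missing, c(0, 1))
})

test_that("background comparison is calibrated and detects planted structure", {
  set.seed(21)
  chromSizes <- c(chr1 = 2e6, chr2 = 2e6)
  regions <- GRanges(sample(names(chromSizes), 60, replace = TRUE),
                     IRanges(start = sample.int(1.9e6, 60), width = 2000))
  # planted: repeats only inside the regions; neutral: uniform everywhere
  planted <- regions[sample(60, 50)]
  planted <- GRanges(seqnames(planted),
                     IRanges(start(planted) + 500, width = 100))
  neutral <- GRanges(sample(names(chromSizes), 300, replace = TRUE),
                     IRanges(sample.int(2e6 - 100, 300), width = 100))
  rep_ <- backgroundComparison(regions, list(
    featureTrack("planted", "count", "inside", planted),
    featureTrack("neutral", "count", "inside", neutral)),
    chromSizes, nShuffles = 60, seed = 2)
  expect_lt(rep_$p_bonferroni[rep_$feature == "planted"], 0.001)
  expect_gt(rep_$z[rep_$feature == "planted"], 0)
  expect_gt(rep_$p[rep_$feature == "neutral"], 0.01)
  expect_error(backgroundComparison(regions, list(
    featureTrack("planted", "count", "inside", planted)),
    chromSizes, nShuffles = 1), "at least 2")
})

test_that("a constant genome-wide feature gets z = 0 and p = 1", {
  chromSizes <- c(chr1 = 1e6)
  regions <- GRanges("chr1", IRanges(c(1001, 50001), width = 1000))
  cover <- GRanges("chr1", IRanges(1, 1e6))
  mcols(cover)$score <- 5
  rep_ <- backgroundComparison(regions, list(
    featureTrack("flat", "mean", "inside", cover)),
    chromSizes, nShuffles = 10, seed = 3)
  expect_equal(rep_$z, 0)
  expect_equal(rep_$p, 1)
})

test_that("breakpoint windows sit at the documented offsets", {
  reg <- GRanges("chr1", IRanges(10001, 20000))   # breakpoints 10000/20000 (0-based)
  # inside windows for the left breakpoint: [b, b+49] at offset -50, etc.
  w <- .offsetWindows(reg, -50, 50)
  expect_equal(start(w), c(10001, 19951))
  expect_equal(end(w), c(10050, 20000))
  w2 <- .offsetWindows(reg, -250, 50)
  expect_equal(start(w2), c(10201, 19751))
  w3 <- .offsetWindows(reg, 0, 50)    # just outside
  expect_equal(start(w3), c(9951, 20001))
  expect_equal(end(w3), c(10000, 20050))
  w4 <- .offsetWindows(reg, 1450, 50)
  expect_equal(start(w4), c(8501, 21451))
  # window count audit: 2 x (nInside + nOutside) windows per long region
  prof <- breakpointWindowProfile(reg, GRanges(), nRandom = 0)
  expect_equal(nrow(prof$profile), 35)
  expect_equal(sum(prof$profile$n_windows), 2 * 35)
  # short regions contribute only the inside windows that fit
  short <- GRanges("chr1", IRanges(10001, 10160))   # 160 bp
  profS <- breakpointWindowProfile(short, GRanges(), nRandom = 0)
  inside <- profS$profile[profS$profile$offset < 0, ]
  expect_equal(inside$n_windows[inside$offset == -50], 2)
  expect_equal(inside$n_windows[inside$offset == -250], 0)
})

test_that("planted breakpoint repeats produce a spike at offset [0;49]", {
  set.seed(8)
  chromSizes <- c(chr1 = 5e6)
  starts <- sort(sample.int(4.8e6, 40))
  starts <- starts[c(TRUE, diff(starts) > 4000)]
  reg <- GRanges("chr1", IRanges(starts + 1, starts + 2000))
  # one repeat placed right at every left breakpoint, just outside
  reps <- GRanges("chr1", IRanges(starts - 20, starts - 1))
  prof <- breakpointWindowProfile(reg, reps, nRandom = 5,
                                  chromSizes = chromSizes, seed = 4)
  p <- prof$profile
  at0 <- p$frequency[p$offset == 0]
  expect_equal(at0, length(reg) / (2 * length(reg)), tolerance = 1e-9)
  expect_gt(at0, max(prof$background[, "0"]))
  # empty repeat track -> all-zero profile
  empty <- breakpointWindowProfile(reg, GRanges(), nRandom = 0)
  expect_true(all(empty$profile$frequency == 0))
})

test_that("RF permutation p-values flag a causal feature and stay uniform under the null", {
  set.seed(14)
  n <- 150
  X <- data.frame(causal = rnorm(n), a = rnorm(n), b = rnorm(n),
                  c = rnorm(n))
  y <- X$causal
  res <- rfImportance(X, y, nTrees = 100, nPerm = 120, seed = 2)
  expect_lte(res$importance$p_empirical[res$importance$feature == "causal"],
             1 / 120)
  expect_gt(res$r2_cv, 0.5)
  expect_error(rfImportance(X, rep(1, n), nPerm = 10), "constant")
  expect_error(rfImportance(X, y, nPerm = 0), "at least 1")

  # null response: empirical p-values approximately uniform across noise
  # features (KS test not rejecting at alpha = 0.01)
  set.seed(15)
  Xn <- as.data.frame(matrix(rnorm(120 * 12), 120, 12))
  yn <- rnorm(120)
  resN <- rfImportance(Xn, yn, nTrees = 60, nPerm = 150, seed = 3)
  ks <- suppressWarnings(stats::ks.test(resN$importance$p_empirical,
                                        "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("partial Spearman nulls out a confounded feature", {
  set.seed(4)
  n <- 2000
  A <- rnorm(n)
  B <- A + rnorm(n, sd = 0.5)     # proxy of A, no direct effect
  y <- A + rnorm(n, sd = 0.5)
  res <- partialSpearman(data.frame(A = A, B = B), y)
  rB <- res[res$feature == "B", ]
  rA <- res[res$feature == "A", ]
  expect_gt(stats::cor(rank(B), rank(y)), 0.4)   # simple correlation present
  expect_lt(abs(rB$rho_partial), 0.08)           # partial ~ 0
  expect_gt(rA$rho_partial, 0.5)
  expect_gt(rB$p, 0.001)
  expect_lt(rA$p, 1e-10)
  expect_true(rA$ci_lo < rA$rho_partial && rA$rho_partial < rA$ci_hi)
})

test_that("partial and simple correlations agree for independent features", {
  set.seed(6)
  n <- 1500
  X <- data.frame(u = rnorm(n), v = rnorm(n), w = rnorm(n))
  y <- 0.5 * X$u + rnorm(n)
  res <- partialSpearman(X, y)
  expect_true(all(abs(res$rho_partial - res$rho_simple) < 0.06))
  # single perfectly monotone feature: both coefficients = 1
  res1 <- partialSpearman(data.frame(x = 1:50), exp(1:50 / 10))
  expect_equal(res1$rho_partial, 1)
  expect_equal(res1$rho_simple, 1)
  # collinear block errors
  Z <- data.frame(a = X$u, b = X$u)
  expect_error(partialSpearman(Z, y), "collinear|disagree")
})
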