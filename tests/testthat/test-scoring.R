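bgModelFor <- function(tMin = 0, tMax = 100, eps = 0.001)
    new("BackgroundModel", size = 2, prob = 0.5, tMin = tMin, tMax = tMax,
        eps = eps)

test_that("pi estimate: formula, clamping, input checks", {
    pr <- estimatePi(0.1, 1e6, 1e9)
    expect_equal(pr@pi, 9e-4)
    expect_equal(estimatePi(0, 1e9, 1e9)@pi, 1 - 1e-6)  # clamped
    expect_error(estimatePi(1, 1e6, 1e9), "fdr")
    expect_error(estimatePi(0.1, 0, 1e9), "peakLength")
})

test_that("posterior identities: sigmoid at pi = 0.5, shape cancellation", {
    pk <- mkPeaks("chr1", c(5000L, 9000L))
    x <- matrix(c(5L, 3L, 0L, 2L, 10L, 1L, 1L, 0L), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("p01", "p02"), NULL))
    counts <- new("PeakBinCounts", counts = x, window = 40L, bin = 10L,
                  nBins = 4L, nStrands = 1L, nSamples = 1L,
                  shapeUsable = c(TRUE, TRUE))
    bg <- bgModelFor()
    a0 <- runif(4, 0.5, 2)
    sc <- scorePeaks(pk, counts, bg, a0, a0, 0.5)  # alpha0 == alpha1
    # shape terms cancel; logLR is the total-count term alone
    T <- peakTotals(counts)
    expect_equal(mcols(sc)$logLR, unname(logF1(T, bg) - logF0(T, bg)))
    expect_equal(mcols(sc)$posterior, plogis(mcols(sc)$logLR))
    # shape-excluded peaks keep only the count term even when alphas differ
    counts2 <- counts
    counts2@shapeUsable <- c(FALSE, FALSE)
    sc2 <- scorePeaks(pk, counts2, bg, a0, rev(a0) * 2, 0.5)
    expect_equal(mcols(sc2)$logLR, mcols(sc)$logLR)
})

test_that("out-of-range totals give posterior 0 and cannot out-rank", {
    pk <- mkPeaks("chr1", c(5000L, 9000L))
    x <- matrix(c(200L, 120L, 2L, 1L), nrow = 2, byrow = TRUE,
                dimnames = list(c("p01", "p02"), NULL))
    counts <- new("PeakBinCounts", counts = x, window = 20L, bin = 10L,
                  nBins = 2L, nStrands = 1L, nSamples = 1L,
                  shapeUsable = c(TRUE, TRUE))
    bg <- bgModelFor(tMin = 0, tMax = 100)  # first peak's T = 320 > tMax
    sc <- scorePeaks(pk, counts, bg, c(1, 1), c(2, 1), 0.5)
    expect_equal(mcols(sc)$posterior[1], 0)
    expect_identical(mcols(sc)$logLR[1], -Inf)
    rk <- rankPeaks(sc)
    expect_equal(mcols(rk)$id, c("p02", "p01"))
})

test_that("shifting counts toward the alpha1-favoured slot never lowers logLR", {
    # brute force over every split of T = 20 between two slots; the two
    # shape priors share a concentration so only the mean shape differs
    bg <- bgModelFor(tMin = 0, tMax = 30)
    a0 <- c(4, 4)      # background: even shape
    a1 <- c(6, 2)      # binding favours slot 1
    T <- 20L
    lr <- vapply(0:T, function(k) {
        x <- matrix(c(k, T - k), 1L)
        unname(logF1(T, bg) - logF0(T, bg) +
               logDirichletMultinomial(x, a1) -
               logDirichletMultinomial(x, a0))
    }, numeric(1))
    expect_true(all(diff(lr) >= -1e-12))
})

test_that("ranking: posterior ties broken by logLR, deterministic order", {
    pk <- mkPeaks("chr1", c(1000L, 2000L, 3000L, 4000L))
    mcols(pk)$posterior <- c(1, 1, 0.4, 0.4)
    mcols(pk)$logLR <- c(40, 50, 2, 2)
    mcols(pk)$totalCount <- c(10, 10, 8, 9)
    rk <- rankPeaks(pk)
    # saturated posteriors: higher logLR first; equal logLR: higher T first
    expect_equal(mcols(rk)$id, c("p02", "p01", "p04", "p03"))
    expect_equal(mcols(rk)$newRank, 1:4)
    # input permutation does not change the assigned ranks
    perm <- c(3L, 1L, 4L, 2L)
    rk2 <- rankPeaks(pk[perm])
    expect_equal(mcols(rk2)$id, mcols(rk)$id)
    expect_setequal(mcols(rk2)$newRank, seq_along(pk))
})

test_that("ranking is invariant to the prior pi", {
    set.seed(8)
    pk <- mkPeaks("chr1", seq(10000L, 10000L + 99L * 2000L, by = 2000L))
    x <- matrix(rpois(100 * 8, 4), nrow = 100,
                dimnames = list(mcols(pk)$id, NULL))
    counts <- new("PeakBinCounts", counts = x, window = 80L, bin = 10L,
                  nBins = 8L, nStrands = 1L, nSamples = 1L,
                  shapeUsable = rep(TRUE, 100))
    bg <- bgModelFor(tMin = min(rowSums(x)), tMax = max(rowSums(x)))
    a0 <- rep(1, 8); a1 <- c(4, 3, 2, 1, 1, 1, 1, 1)
    orders <- lapply(c(1e-4, 1e-2, 0.5), function(p)
        mcols(rankPeaks(scorePeaks(pk, counts, bg, a0, a1, p)))$id)
    expect_identical(orders[[1]], orders[[2]])
    expect_identical(orders[[2]], orders[[3]])
})

test_that("reduced model: collapse conserves totals and nests in the full", {
    set.seed(14)
    x <- matrix(rpois(6 * 40, 3), nrow = 6,
                dimnames = list(sprintf("p%02d", 1:6), NULL))
    counts <- new("PeakBinCounts", counts = x, window = 100L, bin = 10L,
                  nBins = 10L, nStrands = 2L, nSamples = 2L,
                  shapeUsable = rep(TRUE, 6))
    red <- collapseToSampleTotals(counts)
    expect_equal(peakTotals(red), peakTotals(counts))
    expect_equal(dim(binCounts(red)), c(6L, 2L))
    # the reduced entry point equals the full machinery on 2-slot vectors
    bg <- bgModelFor(tMin = 0, tMax = max(peakTotals(counts)))
    b0 <- c(1.5, 1.5); b1 <- c(4, 1)
    pk <- mkPeaks("chr1", seq(5000L, by = 3000L, length.out = 6L),
                  ids = rownames(x))
    full <- scorePeaks(pk, red, bg, b0, b1, 0.3)
    viaReduced <- reducedModelScore(binCounts(red)[, 1], binCounts(red)[, 2],
                                    bg, b0, b1, 0.3)
    expect_equal(mcols(full)$posterior, viaReduced$posterior)
    expect_equal(mcols(full)$logLR, viaReduced$logLR)
})
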