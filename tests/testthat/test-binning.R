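test_that("reads land in the bin holding their 5' base, half-open window", {
    pk <- mkPeaks("chr1", 10000L)
    w <- 800L; b <- 10L; m <- w %/% b
    # forward read whose 5' base sits exactly at summit - w/2 -> bin 1 (fwd)
    rplus <- mkReads("chr1", 10000L - w / 2, 36L, "+")
    bc <- binPeakCounts(pk, rplus, window = w, bin = b)
    expect_equal(sum(binCounts(bc)), 1L)
    expect_equal(binCounts(bc)[1, "IP.fwd.001"], c(p01 = 1L),
                 ignore_attr = TRUE)
    expect_equal(peakTotals(bc), c(p01 = 1))

    # reverse read with 5' base (its end) exactly at summit + w/2: excluded
    rminus <- mkReads("chr1", 10000L + w / 2 - 35L, 36L, "-")
    bc2 <- binPeakCounts(pk, rminus, window = w, bin = b)
    expect_equal(sum(binCounts(bc2)), 0L)
    # one base further left it lands in the last reverse bin
    rminus2 <- GenomicRanges::shift(rminus, -1L)
    bc3 <- binPeakCounts(pk, rminus2, window = w, bin = b)
    expect_equal(binCounts(bc3)[1, sprintf("IP.rev.%03d", m)],
                 c(x = 1L), ignore_attr = TRUE)
})

test_that("replicate IP samples are pooled into one slot", {
    pk <- mkPeaks("chr1", 10000L)
    rep1 <- mkReads("chr1", rep(10000L, 3L), 36L, "+")
    rep2 <- mkReads("chr1", rep(10000L, 3L), 36L, "+")
    bc <- binPeakCounts(pk, list(rep1, rep2))
    expect_equal(max(binCounts(bc)), 6L)
    expect_equal(sum(binCounts(bc)), 6L)
})

test_that("bin counts conserve reads and are translation invariant", {
    set.seed(42)
    for (rep in 1:5) {
        summit <- 50000L
        n <- 200L
        pos <- summit + sample(-600:600, n, replace = TRUE)
        strand <- sample(c("+", "-"), n, replace = TRUE)
        start1 <- ifelse(strand == "+", pos, pos - 35L)
        reads <- mkReads("chr1", start1, 36L, strand)
        pk <- mkPeaks("chr1", summit)
        bc <- binPeakCounts(pk, reads)
        # conservation: total count equals reads whose 5' base is in-window
        p0 <- ifelse(strand == "+", start1 - 1L, start1 + 35L)
        inWin <- p0 >= summit - 1L - 400L & p0 < summit - 1L + 400L
        expect_equal(sum(binCounts(bc)), sum(inWin))
        # translation invariance
        off <- 12345L
        bcShift <- binPeakCounts(mkPeaks("chr1", summit + off),
                                 GenomicRanges::shift(reads, off))
        expect_equal(binCounts(bcShift), binCounts(bc),
                     ignore_attr = TRUE)
    }
})

test_that("one bin per strand per sample reduces to strand totals", {
    set.seed(7)
    summit <- 20000L
    pos <- summit + sample(-390:390, 120L, replace = TRUE)
    strand <- sample(c("+", "-"), 120L, replace = TRUE)
    start1 <- ifelse(strand == "+", pos, pos - 35L)
    reads <- mkReads("chr1", start1, 36L, strand)
    pk <- mkPeaks("chr1", summit)
    wide <- binPeakCounts(pk, reads, window = 800L, bin = 800L)
    fine <- binPeakCounts(pk, reads, window = 800L, bin = 10L)
    expect_equal(ncol(binCounts(wide)), 2L)
    expect_equal(binCounts(wide)[1, "IP.fwd.001"],
                 sum(binCounts(fine)[1, grepl("fwd", colnames(binCounts(fine)))]),
                 ignore_attr = TRUE)
    expect_equal(sum(binCounts(wide)), sum(binCounts(fine)))
})

test_that("chromosome-end windows are flagged shape-unusable", {
    pk <- mkPeaks("chr1", 300L)  # window would start at -100
    reads <- mkReads("chr1", 250L, 36L, "+")
    expect_warning(
        bc <- binPeakCounts(pk, reads, chromLengths = c(chr1 = 100000)),
        "truncated")
    expect_false(shapeUsable(bc)[1])
})

test_that("zero-run filter removes runs of >= 5 zeros and keeps shorter", {
    expect_identical(filterZeroRuns(c(3, 0, 0, 0, 0, 0, 2)), c(3, 2))
    expect_identical(filterZeroRuns(c(1, 0, 0, 0, 0, 2)),
                     c(1, 0, 0, 0, 0, 2))
    expect_identical(filterZeroRuns(c(0, 0, 0, 0, 0)), numeric(0))
    expect_identical(filterZeroRuns(c(2, 0, 0, 0, 0, 0, 0, 0, 1, 0)),
                     c(2, 1, 0))
})

test_that("background harvest excludes peaks and applies the zero filter", {
    # 10 kb chromosome, one peak interval masking its window
    chromLengths <- c(chr1 = 10000)
    pk <- mkPeaks("chr1", 5000L, half = 400L)
    # reads in two background windows plus the peak
    reads <- c(mkReads("chr1", c(100L, 150L, 9000L), 36L, "+"),
               mkReads("chr1", rep(5000L, 20L), 36L, "+"))
    bg <- harvestBackgroundWindows(pk, reads, chromLengths, window = 800L)
    expect_true(all(width(bg) == 800L))
    expect_equal(length(GenomicRanges::findOverlaps(bg, pk)), 0L)
    # each flank holds a zero run of only 4, so nothing is filtered even
    # though the runs would join into >= 5 if blocks were concatenated
    expect_equal(mcols(bg)$total, c(2, 0, 0, 0, 0, 0, 0, 0, 0, 1))
    expect_error(
        harvestBackgroundWindows(pk, mkReads("chr1", 5000L, 36L, "+"),
                                 chromLengths, window = 800L),
        "zero-run")
})

test_that("background interval sampling is seeded and peak-disjoint", {
    chromLengths <- c(chr1 = 60000)
    pk <- mkPeaks("chr1", 30000L, half = 400L)
    set.seed(99)
    pos <- sample(1:59000, 3000L, replace = TRUE)
    strand <- sample(c("+", "-"), 3000L, replace = TRUE)
    reads <- mkReads("chr1", pos, 36L, strand)
    bg <- harvestBackgroundWindows(pk, reads, chromLengths)
    v1 <- sampleBackgroundIntervals(bg, reads, n = 20L, seed = 5L)
    v2 <- sampleBackgroundIntervals(bg, reads, n = 20L, seed = 5L)
    expect_identical(binCounts(v1), binCounts(v2))
    expect_error(sampleBackgroundIntervals(bg, reads, n = 0L), "n must be")
    expect_warning(sampleBackgroundIntervals(bg, reads, n = 10000L,
                                             seed = 1L), "replacement")
})
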