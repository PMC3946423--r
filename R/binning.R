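#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

## slot layout: (sample: IP, control) x (strand: fwd, rev) x (bin: left->right)
.slotNames <- function(nBins, nStrands, nSamples) {
    samples <- c("IP", "control")[seq_len(nSamples)]
    strands <- c("fwd", "rev")[seq_len(nStrands)]
    as.vector(vapply(samples, function(sa)
        vapply(strands, function(st)
            sprintf("%s.%s.%03d", sa, st, seq_len(nBins)), character(nBins)),
        character(nBins * nStrands)))
}

#' Bin strand-separated read counts around peak summits
#'
#' For each peak, takes the \code{window}-bp window centred on the summit,
#' divides it into \code{window/bin} equal non-overlapping bins, and counts
#' reads per bin separately by strand and by sample (IP first, then control).
#' A read is assigned to the bin containing its 5'-most aligned base (the
#' start for forward reads, the end for reverse reads), which preserves the
#' bimodal strand-shifted pattern at true binding sites. Replicates passed as
#' a list are pooled into a single IP (or control) slot.
#'
#' Peaks whose window runs off a chromosome end (detectable only when
#' \code{chromLengths} is supplied) are flagged shape-unusable and later
#' scored by the total-count component alone.
#'
#' @param peaks a \code{GRanges} with \code{summit} and \code{id} metadata
#'   columns (see [readPeaks()]).
#' @param ip IP-sample reads: a \code{GRanges} or list of \code{GRanges}
#'   (replicates, pooled).
#' @param control optional control-sample reads, same conventions.
#' @param window window width in bp (default 800); must be even.
#' @param bin bin width in bp (default 10); must divide \code{window}.
#' @param chromLengths optional named vector of chromosome lengths used to
#'   flag windows truncated by chromosome ends.
#' @return a \linkS4class{PeakBinCounts}.
#' @export
binPeakCounts <- function(peaks, ip, control = NULL, window = 800L,
                          bin = 10L, chromLengths = NULL) {
    window <- as.integer(window); bin <- as.integer(bin)
    if (window %% 2L != 0L) stop("window width must be even", call. = FALSE)
    if (window %% bin != 0L)
        stop("bin width must divide window width", call. = FALSE)
    m <- window %/% bin
    if (m < 1L) stop("window must contain at least one bin", call. = FALSE)
    mc <- mcols(peaks)
    if (is.null(mc$summit) || is.null(mc$id))
        stop("peaks need 'summit' and 'id' metadata columns", call. = FALSE)
    samples <- list(IP = .poolReads(ip, "ip"))
    if (!is.null(control)) samples$control <- .poolReads(control, "control")
    nSamples <- length(samples)
    n <- length(peaks)
    K <- m * 2L * nSamples
    half <- window %/% 2L

    summit0 <- mc$summit - 1L
    winStart0 <- summit0 - half           # 0-based half-open [start, start+w)
    winGR <- GRanges(seqnames(peaks), IRanges(winStart0 + 1L,
                                              winStart0 + window))
    shapeOK <- rep(TRUE, n)
    if (!is.null(chromLengths)) {
        len <- chromLengths[as.character(seqnames(peaks))]
        shapeOK <- !is.na(len) & winStart0 >= 0L &
            (winStart0 + window) <= len
        if (any(!shapeOK))
            warning(sum(!shapeOK),
                    " peak window(s) truncated by chromosome ends; ",
                    "these peaks are scored by total count only",
                    call. = FALSE)
    } else if (any(winStart0 < 0L)) {
        shapeOK <- winStart0 >= 0L
        warning(sum(!shapeOK),
                " peak window(s) truncated at a chromosome start; ",
                "scored by total count only", call. = FALSE)
    }

    acc <- numeric(n * K)
    for (s in seq_len(nSamples)) {
        reads <- samples[[s]]
        strandChr <- as.character(strand(reads))
        p0 <- .fivePrime0(reads)
        for (st in 1:2) {
            keep <- strandChr == c("+", "-")[st]
            if (!any(keep)) next
            pos <- GRanges(seqnames(reads)[keep],
                           IRanges(p0[keep] + 1L, width = 1L))
            hits <- findOverlaps(pos, winGR, ignore.strand = TRUE)
            if (length(hits) == 0L) next
            w <- subjectHits(hits)
            b <- (p0[keep][queryHits(hits)] - winStart0[w]) %/% bin
            col <- ((s - 1L) * 2L + (st - 1L)) * m + b + 1L
            idx <- (col - 1L) * n + w
            acc <- acc + tabulate(idx, nbins = n * K)
        }
    }
    counts <- matrix(as.integer(acc), nrow = n, ncol = K,
                     dimnames = list(mc$id, .slotNames(m, 2L, nSamples)))
    new("PeakBinCounts", counts = counts, window = window, bin = bin,
        nBins = m, nStrands = 2L, nSamples = as.integer(nSamples),
        shapeUsable = shapeOK)
}

#' Remove long zero runs from background window counts
#'
#' Unmappable stretches of the genome produce long runs of zero-count
#' background windows that would bias the negative-binomial fit towards
#' zero. Every maximal run of five or more consecutive zero-count windows is
#' removed; shorter zero runs are genuine low-coverage background and are
#' kept.
#'
#' @param totals integer vector of per-window total counts, in genomic order
#'   within one contiguous block.
#' @param minRun minimum zero-run length to remove (default 5).
#' @return the filtered totals vector.
#' @export
filterZeroRuns <- function(totals, minRun = 5L) {
    totals[.zeroRunKeep(totals, minRun)]
}

.zeroRunKeep <- function(totals, minRun = 5L) {
    if (length(totals) == 0L) return(logical(0))
    r <- rle(totals == 0)
    drop <- r$values & r$lengths >= minRun
    rep(!drop, r$lengths)
}

#' Harvest background windows for the total-count fit
#'
#' Tiles the genome outside the candidate peak intervals with non-overlapping
#' \code{window}-bp windows, counts the total reads (all samples and strands
#' pooled, 5' base assignment) in each, and removes maximal runs of five or
#' more consecutive zero-count windows (unmappable territory). The remaining
#' windows feed the negative-binomial moment estimator and the background
#' shape training set.
#'
#' @param peaks candidate peak \code{GRanges}; their intervals are excluded.
#' @param reads a \code{GRanges} or list of \code{GRanges} of all reads (IP
#'   and control pooled).
#' @param chromLengths named vector of chromosome lengths.
#' @param window window width in bp (default 800).
#' @return a \code{GRanges} of retained background windows with metadata
#'   column \code{total}.
#' @export
harvestBackgroundWindows <- function(peaks, reads, chromLengths,
                                     window = 800L) {
    window <- as.integer(window)
    reads <- .poolReads(reads)
    mask <- reduce(peaks, ignore.strand = TRUE)
    winList <- list(); blockList <- list(); blockId <- 0L
    for (chrom in names(chromLengths)) {
        len <- chromLengths[[chrom]]
        chrGR <- GRanges(chrom, IRanges(1L, len))
        gapsGR <- GenomicRanges::setdiff(
            chrGR, mask[seqnames(mask) == chrom], ignore.strand = TRUE)
        for (g in seq_along(gapsGR)) {
            gw <- width(gapsGR)[g]
            k <- gw %/% window
            if (k < 1L) next
            blockId <- blockId + 1L
            st <- start(gapsGR)[g] + window * (seq_len(k) - 1L)
            winList[[length(winList) + 1L]] <-
                GRanges(chrom, IRanges(st, width = window))
            blockList[[length(blockList) + 1L]] <- rep(blockId, k)
        }
    }
    if (length(winList) == 0L)
        stop("no background windows outside the candidate peaks; ",
             "input region too small", call. = FALSE)
    wins <- do.call(c, winList)
    block <- unlist(blockList)
    p0 <- .fivePrime0(reads)
    pos <- GRanges(seqnames(reads), IRanges(p0 + 1L, width = 1L))
    tot <- countOverlaps(wins, pos, ignore.strand = TRUE)
    keep <- unlist(lapply(split(seq_along(tot), block),
                          function(i) i[.zeroRunKeep(tot[i])]),
                   use.names = FALSE)
    keep <- sort(keep)
    if (length(keep) == 0L)
        stop("all background windows removed by the zero-run filter; ",
             "provide more reads or a larger genome", call. = FALSE)
    out <- wins[keep]
    mcols(out)$total <- tot[keep]
    out
}

#' Sample background intervals for shape training
#'
#' Draws \code{n} intervals uniformly at random (seeded) from the zero-run
#' filtered background windows and converts each to a
#' \linkS4class{PeakBinCounts} row exactly as for peaks, with the interval
#' midpoint playing the summit role. These vectors train the background
#' shape parameters.
#'
#' @param bgWindows background windows from [harvestBackgroundWindows()].
#' @param ip,control reads, as in [binPeakCounts()].
#' @param window,bin binning geometry, as in [binPeakCounts()].
#' @param n number of intervals to draw (default 5000). When fewer windows
#'   are available, sampling is with replacement and a warning is issued.
#' @param seed RNG seed (default 1).
#' @return a \linkS4class{PeakBinCounts} of \code{n} background intervals.
#' @export
sampleBackgroundIntervals <- function(bgWindows, ip, control = NULL,
                                      window = 800L, bin = 10L,
                                      n = 5000L, seed = 1L) {
    n <- as.integer(n)
    if (n < 1L) stop("n must be >= 1", call. = FALSE)
    avail <- length(bgWindows)
    if (avail == 0L) stop("no background windows available", call. = FALSE)
    replace <- avail < n
    if (replace)
        warning("only ", avail, " background windows for ", n,
                " requested intervals; sampling with replacement",
                call. = FALSE)
    idx <- .withSeed(seed, sample.int(avail, n, replace = replace))
    sel <- bgWindows[idx]
    mid0 <- (start(sel) - 1L) + width(sel) %/% 2L  # 0-based midpoint
    pseudo <- GRanges(seqnames(sel), IRanges(start(sel), end(sel)))
    mcols(pseudo)$summit <- mid0 + 1L
    mcols(pseudo)$id <- sprintf("bg_%06d", seq_len(n))
    binPeakCounts(pseudo, ip = ip, control = control, window = window,
                  bin = bin)
}
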