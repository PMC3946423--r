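#' Score and rank candidate peaks end to end
#'
#' Runs the full two-step re-ranking workflow on in-memory objects: bin the
#' reads around each candidate summit, fit the negative-binomial background
#' to non-peak windows, learn the background and binding Polya shape
#' parameters by MM, and rank the peaks by posterior probability. With
#' \code{reduced = TRUE} the identical machinery runs on per-sample totals
#' only (no shape information), which is the controlled comparison for
#' quantifying the net gain of modelling peak shape.
#'
#' @param peaks candidate \code{GRanges} from [readPeaks()] (or the
#'   simulator), with \code{summit}, \code{sourceRank}, \code{id}.
#' @param ip,control IP / control reads (\code{GRanges} or list of
#'   replicates; replicates are pooled).
#' @param chromLengths named vector of chromosome lengths.
#' @param effectiveGenomeLength mappable genome length G used for the prior;
#'   defaults to \code{sum(chromLengths)}.
#' @param fdr first-step FDR estimate (default 0.1).
#' @param window,bin binning geometry (defaults 800 and 10 bp).
#' @param eps uniform outlier weight of the background mixture (default
#'   0.001).
#' @param n0 number of background shape-training intervals (default 5000).
#' @param n1 number of top-ranked training peaks for the binding shape
#'   (default 2000).
#' @param seed RNG seed for the background interval sampling (default 1).
#' @param tol,maxIter MM convergence settings.
#' @param reduced run the reduced (shape-free) model instead.
#' @return a list with \code{ranked} (sorted \code{GRanges} with
#'   \code{posterior}, \code{logLR}, \code{totalCount}, \code{newRank}),
#'   \code{report} (fitted parameters), and \code{models}
#'   (\code{background}, \code{alpha0}, \code{alpha1}, \code{prior},
#'   \code{counts}).
#' @export
scoreChipPeaks <- function(peaks, ip, control = NULL, chromLengths,
                           effectiveGenomeLength = sum(chromLengths),
                           fdr = 0.1, window = 800L, bin = 10L,
                           eps = 0.001, n0 = 5000L, n1 = 2000L,
                           seed = 1L, tol = 1e-8, maxIter = 1000L,
                           reduced = FALSE) {
    if (length(peaks) == 0L) stop("empty candidate peak list", call. = FALSE)
    counts <- binPeakCounts(peaks, ip, control, window = window, bin = bin,
                            chromLengths = chromLengths)
    allReads <- if (is.null(control)) .poolReads(ip)
                else c(.poolReads(ip), .poolReads(control))
    bgWin <- harvestBackgroundWindows(peaks, allReads, chromLengths,
                                      window = window)
    bgModel <- fitBackgroundModel(bgWin, peakTotals(counts), eps = eps)
    bgVec <- sampleBackgroundIntervals(bgWin, ip, control, window = window,
                                       bin = bin, n = n0, seed = seed)
    if (reduced) {
        countsUse <- collapseToSampleTotals(counts)
        bgVecUse <- collapseToSampleTotals(bgVec)
    } else {
        countsUse <- counts
        bgVecUse <- bgVec
    }
    alpha0 <- estimateAlpha0(bgVecUse, tol = tol, maxIter = maxIter)
    alpha1 <- estimateAlpha1(countsUse, mcols(peaks)$sourceRank, n1 = n1,
                             tol = tol, maxIter = maxIter)
    peakLength <- sum(width(reduce(peaks, ignore.strand = TRUE)))
    prior <- estimatePi(fdr, peakLength,
                        max(effectiveGenomeLength, peakLength))
    ranked <- rankPeaks(scorePeaks(peaks, countsUse, bgModel, alpha0,
                                   alpha1, prior))
    report <- list(
        nPeaks = length(peaks),
        nReads = length(allReads),
        window = window, bin = bin, eps = eps,
        reduced = reduced, seed = seed, n0 = n0, n1 = n1, fdr = fdr,
        nBackgroundWindows = length(bgWin),
        nb = list(size = bgModel@size, prob = bgModel@prob,
                  mean = bgModel@size * (1 - bgModel@prob) / bgModel@prob),
        uniformBounds = c(bgModel@tMin, bgModel@tMax),
        pi = prior@pi,
        alpha0 = list(concentration = concentration(alpha0),
                      iterations = alpha0@iterations,
                      converged = alpha0@converged),
        alpha1 = list(concentration = concentration(alpha1),
                      iterations = alpha1@iterations,
                      converged = alpha1@converged))
    list(ranked = ranked, report = report,
         models = list(background = bgModel, alpha0 = alpha0,
                       alpha1 = alpha1, prior = prior, counts = countsUse))
}

#' Rank a peak list from files (command path)
#'
#' File-in / file-out wrapper around [scoreChipPeaks()]: reads the candidate
#' peaks, the IP and control BED files and the chromosome-sizes table,
#' scores and ranks, writes the ranked table and a JSON run report with all
#' fitted parameters.
#'
#' @param peaksFile candidate peak file.
#' @param peakFormat \code{"narrowPeak"} or \code{"summitBed"}.
#' @param ipFiles,controlFiles character vectors of BED6 read files
#'   (replicates pooled); \code{controlFiles} may be \code{NULL}.
#' @param chromSizesFile two-column chromosome sizes table.
#' @param outFile output path for the ranked TSV.
#' @param reportFile optional output path for the JSON run report.
#' @param effectiveGenomeLength,fdr,window,bin,eps,n0,n1,seed,tol,maxIter,reduced
#'   passed to [scoreChipPeaks()].
#' @return invisibly, the [scoreChipPeaks()] result.
#' @export
runPeakRanking <- function(peaksFile, peakFormat = "narrowPeak",
                           ipFiles, controlFiles = NULL, chromSizesFile,
                           outFile, reportFile = NULL,
                           effectiveGenomeLength = NULL, fdr = 0.1,
                           window = 800L, bin = 10L, eps = 0.001,
                           n0 = 5000L, n1 = 2000L, seed = 1L, tol = 1e-8,
                           maxIter = 1000L, reduced = FALSE) {
    peaks <- readPeaks(peaksFile, peakFormat)
    ip <- lapply(ipFiles, readBedReads)
    control <- if (length(controlFiles)) lapply(controlFiles, readBedReads)
    chromLengths <- readChromSizes(chromSizesFile)
    if (is.null(effectiveGenomeLength))
        effectiveGenomeLength <- sum(chromLengths)
    res <- scoreChipPeaks(peaks, ip, control, chromLengths,
                          effectiveGenomeLength = effectiveGenomeLength,
                          fdr = fdr, window = window, bin = bin, eps = eps,
                          n0 = n0, n1 = n1, seed = seed, tol = tol,
                          maxIter = maxIter, reduced = reduced)
    writeRankedTable(res$ranked, outFile)
    if (!is.null(reportFile))
        jsonlite::write_json(res$report, reportFile, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    invisible(res)
}

#' Simulate a dataset and write it to disk (command path)
#'
#' Wrapper around [simulateChipSeq()] + [writeSimulation()] mirroring
#' [runPeakRanking()]'s file interface.
#'
#' @param dir output directory.
#' @param cfg a [simConfig()].
#' @return invisibly, the named vector of written paths.
#' @export
runSimulation <- function(dir, cfg = simConfig()) {
    writeSimulation(simulateChipSeq(cfg), dir)
}
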