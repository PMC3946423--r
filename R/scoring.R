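#' Estimate the prior binding probability
#'
#' \eqn{\hat\pi = (1 - \widehat{FDR}) \cdot L / G}: the expected fraction of
#' mappable genome covered by true binding sites among the candidates, from
#' the first-step caller's FDR estimate, the total candidate peak length L
#' and the effective (mappable) genome length G. The estimate is clamped to
#' \code{[1e-6, 1-1e-6]}. Because pi enters every peak's posterior through
#' the same logit offset, its value never changes the final ranking — only
#' the absolute posterior scale.
#'
#' @param fdr first-step FDR estimate in \code{[0, 1)}.
#' @param peakLength total candidate peak length in bp.
#' @param genomeLength effective genome length in bp.
#' @return a \linkS4class{PriorModel}.
#' @export
estimatePi <- function(fdr, peakLength, genomeLength) {
    if (fdr < 0 || fdr >= 1) stop("fdr must lie in [0,1)", call. = FALSE)
    if (peakLength <= 0 || genomeLength <= 0 || peakLength > genomeLength)
        stop("need 0 < peakLength <= genomeLength", call. = FALSE)
    pi <- (1 - fdr) * peakLength / genomeLength
    pi <- min(max(pi, 1e-6), 1 - 1e-6)
    new("PriorModel", pi = pi, fdr = fdr, peakLength = peakLength,
        genomeLength = genomeLength)
}

## core posterior machinery shared by the full and reduced models
.posteriorCore <- function(counts, shapeOK, bg, alpha0, alpha1, prior) {
    a0 <- if (is(alpha0, "PolyaParams")) alpha0@alpha else as.numeric(alpha0)
    a1 <- if (is(alpha1, "PolyaParams")) alpha1@alpha else as.numeric(alpha1)
    if (length(a0) != ncol(counts) || length(a1) != ncol(counts))
        stop(sprintf(
            "dimension mismatch: %d count slots vs alpha0/alpha1 of length %d/%d",
            ncol(counts), length(a0), length(a1)), call. = FALSE)
    T <- rowSums(counts)
    lrT <- logF1(T, bg) - logF0(T, bg)
    shape <- numeric(nrow(counts))
    if (any(shapeOK))
        shape[shapeOK] <-
            logDirichletMultinomial(counts[shapeOK, , drop = FALSE], a1) -
            logDirichletMultinomial(counts[shapeOK, , drop = FALSE], a0)
    logLR <- lrT + shape
    piv <- if (is(prior, "PriorModel")) prior@pi else as.numeric(prior)
    posterior <- plogis(qlogis(piv) + logLR)
    posterior[logLR == -Inf] <- 0
    list(posterior = unname(posterior), logLR = unname(logLR),
         totalCount = unname(T))
}

#' Score candidate peaks under the hierarchical model
#'
#' Computes, for every candidate peak, the posterior probability of being a
#' true binding site and its log likelihood ratio. The log likelihood ratio
#' decomposes into the total-count evidence \code{logF1(T) - logF0(T)} and
#' the peak-shape evidence \code{logMP(x | alpha1) - logMP(x | alpha0)}; the
#' posterior is \code{sigmoid(logit(pi) + logLR)}, evaluated in log space.
#' Peaks flagged shape-unusable contribute only the total-count term. A peak
#' whose total falls outside the uniform support \code{[tMin, tMax]} (possible
#' when scoring new peaks under a frozen model) gets posterior 0 and cannot
#' out-rank any in-range peak.
#'
#' @param peaks candidate peak \code{GRanges} (with \code{summit},
#'   \code{sourceRank}, \code{id}).
#' @param counts the matching \linkS4class{PeakBinCounts}.
#' @param bg a \linkS4class{BackgroundModel}.
#' @param alpha0,alpha1 background and binding \linkS4class{PolyaParams}.
#' @param prior a \linkS4class{PriorModel} (or a bare probability).
#' @return \code{peaks} with added metadata columns \code{posterior},
#'   \code{logLR}, \code{totalCount} (unranked; see [rankPeaks()]).
#' @export
scorePeaks <- function(peaks, counts, bg, alpha0, alpha1, prior) {
    stopifnot(is(counts, "PeakBinCounts"))
    if (length(peaks) != nrow(binCounts(counts)))
        stop("peaks and counts have different lengths", call. = FALSE)
    sc <- .posteriorCore(binCounts(counts), shapeUsable(counts), bg,
                         alpha0, alpha1, prior)
    mcols(peaks)$posterior <- sc$posterior
    mcols(peaks)$logLR <- sc$logLR
    mcols(peaks)$totalCount <- sc$totalCount
    peaks
}

#' Rank scored peaks
#'
#' Sorts by posterior probability, descending. Posteriors equal within 1e-12
#' (numerical saturation near 0 or 1) are tie-broken by the log likelihood
#' ratio, descending; any remaining ties by total count, descending, then by
#' genomic position, ascending, so the ranking is a deterministic function of
#' the scored peaks regardless of input order.
#'
#' @param scored output of [scorePeaks()].
#' @return the same \code{GRanges}, sorted, with metadata column
#'   \code{newRank} (1 = best).
#' @export
rankPeaks <- function(scored) {
    mc <- mcols(scored)
    if (is.null(mc$posterior) || is.null(mc$logLR))
        stop("peaks are not scored; run scorePeaks() first", call. = FALSE)
    key <- round(mc$posterior, 12)
    ord <- order(-key, -mc$logLR, -mc$totalCount,
                 as.integer(match(as.character(seqnames(scored)),
                                  unique(as.character(seqnames(scored))))),
                 start(scored), method = "radix")
    out <- scored[ord]
    mcols(out)$newRank <- seq_along(out)
    out
}

#' Collapse bin counts to per-sample totals (reduced model)
#'
#' Drops the shape information: each peak keeps one total per sample (IP
#' count, control count). The same Polya machinery applied to these length-2
#' vectors is the reduced model used to isolate the net contribution of peak
#' shape; with one sample the collapse degenerates to the total alone.
#'
#' @param counts a \linkS4class{PeakBinCounts}.
#' @return a \linkS4class{PeakBinCounts} with \code{nBins = 1},
#'   \code{nStrands = 1}; totals are conserved.
#' @export
collapseToSampleTotals <- function(counts) {
    stopifnot(is(counts, "PeakBinCounts"))
    x <- binCounts(counts)
    S <- counts@nSamples
    per <- ncol(x) %/% S
    grp <- rep(seq_len(S), each = per)
    xs <- vapply(seq_len(S), function(s)
        rowSums(x[, grp == s, drop = FALSE]), numeric(nrow(x)))
    xs <- matrix(as.integer(xs), nrow = nrow(x),
                 dimnames = list(rownames(x),
                                 c("IP", "control")[seq_len(S)]))
    new("PeakBinCounts", counts = xs, window = counts@window,
        bin = counts@window, nBins = 1L, nStrands = 1L,
        nSamples = counts@nSamples,
        shapeUsable = rep(TRUE, nrow(xs)))
}

#' Score a peak under the reduced (shape-free) model
#'
#' The reduced model keeps only the IP and control totals per peak and runs
#' the identical hierarchical machinery with length-2 count vectors, for
#' which the multivariate Polya reduces to a Beta-binomial. It retains the
#' IP-vs-control information but discards the peak shape.
#'
#' @param ipCount,controlCount per-peak IP and control totals (vectorised).
#' @param bg a \linkS4class{BackgroundModel} fitted to the same totals.
#' @param beta0,beta1 length-2 \linkS4class{PolyaParams} fitted by
#'   [fitPolyaMM()] on collapsed background and training vectors.
#' @param prior a \linkS4class{PriorModel} or probability.
#' @return \code{data.frame} with columns \code{posterior}, \code{logLR},
#'   \code{totalCount}.
#' @export
reducedModelScore <- function(ipCount, controlCount, bg, beta0, beta1,
                              prior) {
    x <- cbind(IP = as.numeric(ipCount), control = as.numeric(controlCount))
    if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
    sc <- .posteriorCore(x, rep(TRUE, nrow(x)), bg, beta0, beta1, prior)
    data.frame(posterior = sc$posterior, logLR = sc$logLR,
               totalCount = sc$totalCount)
}
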