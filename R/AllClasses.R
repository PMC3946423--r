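#' @import methods
#' @importFrom stats dnbinom rnbinom rmultinom rgamma runif var plogis qlogis
#' @importFrom utils head
NULL

#' Bin-level read counts around peak summits
#'
#' Container for the observed data of the shape model: one row per candidate
#' peak (or background interval), one column per count slot. Slots are laid
#' out (sample: IP first, then control) x (strand: forward, reverse) x
#' (bin: left to right), so the number of columns is
#' \code{nBins * nStrands * nSamples}. The reduced (shape-free) model uses the
#' same container with \code{nBins = 1} and \code{nStrands = 1}, i.e. one
#' total per sample.
#'
#' @slot counts integer matrix of non-negative bin counts; rownames are peak
#'   ids.
#' @slot window window width in bp centred on the summit.
#' @slot bin bin width in bp; \code{bin} must divide \code{window}.
#' @slot nBins number of bins per strand per sample (\code{window/bin}).
#' @slot nStrands 2 when forward/reverse are counted separately, 1 when
#'   collapsed.
#' @slot nSamples number of samples (1 = IP only, 2 = IP + control).
#' @slot shapeUsable logical per peak; \code{FALSE} for peaks whose window was
#'   truncated by a chromosome end, which are scored by the total-count
#'   component only.
#'
#' @seealso [binPeakCounts()], [collapseToSampleTotals()]
#' @export
setClass("PeakBinCounts",
    representation(
        counts      = "matrix",
        window      = "integer",
        bin         = "integer",
        nBins       = "integer",
        nStrands    = "integer",
        nSamples    = "integer",
        shapeUsable = "logical"
    )
)

setValidity("PeakBinCounts", function(object) {
    msg <- character()
    cnt <- object@counts
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integral")
    K <- object@nBins * object@nStrands * object@nSamples
    if (ncol(cnt) != K)
        msg <- c(msg, sprintf("ncol(counts) = %d but layout implies K = %d",
                              ncol(cnt), K))
    if (length(object@shapeUsable) != nrow(cnt))
        msg <- c(msg, "shapeUsable must have one entry per peak")
    if (object@nBins >= 2L && object@window %% object@bin != 0L)
        msg <- c(msg, "bin width must divide window width")
    if (is.null(rownames(cnt)) || anyDuplicated(rownames(cnt)))
        msg <- c(msg, "counts must have unique rownames (peak ids)")
    if (length(msg)) msg else TRUE
})

#' Background total-count model
#'
#' Mixture model for the total read count T of a candidate peak window:
#' under background, T follows a negative binomial (size, prob) contaminated
#' by a discrete uniform outlier component on \code{[tMin, tMax]} with fixed
#' weight \code{eps}; under binding, T follows the discrete uniform on
#' \code{[tMin, tMax]}. The contamination bounds the total-count likelihood
#' ratio at \code{1/eps}, which keeps outlier windows from dominating the
#' ranking.
#'
#' @slot size negative-binomial size (dispersion) parameter r > 0.
#' @slot prob negative-binomial success probability p in (0,1); the NB mean is
#'   r(1-p)/p.
#' @slot tMin,tMax integer support bounds of the uniform component, taken as
#'   the min and max total count over all candidate peaks.
#' @slot eps mixing weight of the uniform outlier component (default 0.001,
#'   fixed, not estimated).
#' @export
setClass("BackgroundModel",
    representation(
        size = "numeric",
        prob = "numeric",
        tMin = "numeric",
        tMax = "numeric",
        eps  = "numeric"
    ),
    prototype(eps = 0.001)
)

setValidity("BackgroundModel", function(object) {
    msg <- character()
    if (length(object@size) != 1L || !is.finite(object@size) ||
        object@size <= 0) msg <- c(msg, "size must be a positive number")
    if (length(object@prob) != 1L || object@prob <= 0 || object@prob >= 1)
        msg <- c(msg, "prob must lie in (0,1)")
    if (object@tMin > object@tMax) msg <- c(msg, "tMin must be <= tMax")
    if (object@eps < 0 || object@eps > 1)
        msg <- c(msg, "eps must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Dirichlet (multivariate Polya) shape parameters
#'
#' A positive vector alpha of length K, one entry per count slot. The mean
#' shape alpha/sum(alpha) is the expected bin-count profile; the concentration
#' sum(alpha) controls how much individual peaks may deviate from it.
#'
#' @slot alpha positive numeric vector; names follow the PeakBinCounts column
#'   layout.
#' @export
setClass("PolyaParams", representation(alpha = "numeric"))

setValidity("PolyaParams", function(object) {
    if (length(object@alpha) == 0L) return("alpha must be non-empty")
    if (any(!is.finite(object@alpha)) || any(object@alpha <= 0))
        return("alpha entries must be finite and > 0")
    TRUE
})

#' Result of an MM fit of Polya parameters
#'
#' Extends \linkS4class{PolyaParams} with the fit diagnostics: the
#' log-likelihood trace (non-decreasing by the MM construction), the number of
#' iterations, and whether the relative-change convergence criterion was met
#' before the iteration cap.
#'
#' @slot iterations number of MM iterations performed.
#' @slot logLik final log-likelihood.
#' @slot trace per-iteration log-likelihood values.
#' @slot converged TRUE if the relative log-likelihood change dropped below
#'   the tolerance before the iteration cap.
#' @export
setClass("PolyaFit",
    contains = "PolyaParams",
    representation(
        iterations = "integer",
        logLik     = "numeric",
        trace      = "numeric",
        converged  = "logical"
    )
)

#' Prior probability that a candidate peak is a true binding site
#'
#' pi is estimated as (1 - FDR) * L / G where FDR is the first-step caller's
#' FDR estimate, L the total candidate peak length and G the effective
#' (mappable) genome length. pi shifts every posterior by the same logit
#' offset and therefore never changes the peak ranking.
#'
#' @slot pi prior probability, clamped to [1e-6, 1 - 1e-6].
#' @slot fdr first-step FDR estimate used.
#' @slot peakLength total candidate peak length in bp.
#' @slot genomeLength effective genome length in bp.
#' @export
setClass("PriorModel",
    representation(
        pi           = "numeric",
        fdr          = "numeric",
        peakLength   = "numeric",
        genomeLength = "numeric"
    )
)

setValidity("PriorModel", function(object) {
    if (object@pi <= 0 || object@pi >= 1) return("pi must lie in (0,1)")
    TRUE
})

## ---- accessors & show ------------------------------------------------------

#' @describeIn PeakBinCounts the count matrix (peaks x slots).
#' @param object a PeakBinCounts (or model) object.
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))
#' @rdname PeakBinCounts-class
#' @export
setMethod("binCounts", "PeakBinCounts", function(object) object@counts)

#' @describeIn PeakBinCounts per-peak total read count T (row sums).
#' @export
setGeneric("peakTotals", function(object) standardGeneric("peakTotals"))
#' @rdname PeakBinCounts-class
#' @export
setMethod("peakTotals", "PeakBinCounts",
          function(object) rowSums(object@counts))

#' @describeIn PeakBinCounts logical vector: is the peak usable for shape
#'   scoring (window not truncated)?
#' @export
setGeneric("shapeUsable", function(object) standardGeneric("shapeUsable"))
#' @rdname PeakBinCounts-class
#' @export
setMethod("shapeUsable", "PeakBinCounts", function(object) object@shapeUsable)

#' @rdname PeakBinCounts-class
#' @export
setMethod("dim", "PeakBinCounts", function(x) dim(x@counts))

#' @rdname PeakBinCounts-class
#' @param x,i a PeakBinCounts and a row (peak) index.
#' @export
setMethod("[", "PeakBinCounts", function(x, i) {
    initialize(x, counts = x@counts[i, , drop = FALSE],
               shapeUsable = x@shapeUsable[i])
})

setMethod("show", "PeakBinCounts", function(object) {
    cat(sprintf(
        "PeakBinCounts: %d peaks x %d slots (%d bp window, %d bp bins, %d bin(s) x %d strand(s) x %d sample(s))\n",
        nrow(object@counts), ncol(object@counts), object@window, object@bin,
        object@nBins, object@nStrands, object@nSamples))
    cat(sprintf("  total reads: %d; shape-usable peaks: %d/%d\n",
        sum(object@counts), sum(object@shapeUsable),
        length(object@shapeUsable)))
})

#' @describeIn PolyaParams the parameter vector alpha.
#' @param object a PolyaParams object.
#' @export
setGeneric("alpha", function(object) standardGeneric("alpha"))
#' @rdname PolyaParams-class
#' @export
setMethod("alpha", "PolyaParams", function(object) object@alpha)

#' @describeIn PolyaParams total concentration sum(alpha).
#' @export
setGeneric("concentration", function(object) standardGeneric("concentration"))
#' @rdname PolyaParams-class
#' @export
setMethod("concentration", "PolyaParams",
          function(object) sum(object@alpha))

#' @describeIn PolyaParams normalized mean shape alpha/sum(alpha).
#' @export
setGeneric("meanShape", function(object) standardGeneric("meanShape"))
#' @rdname PolyaParams-class
#' @export
setMethod("meanShape", "PolyaParams",
          function(object) object@alpha / sum(object@alpha))

setMethod("show", "PolyaParams", function(object) {
    cat(sprintf("PolyaParams: K = %d, concentration |alpha| = %.4g\n",
                length(object@alpha), sum(object@alpha)))
})

setMethod("show", "PolyaFit", function(object) {
    callNextMethod()
    cat(sprintf("  MM fit: %d iterations, logLik = %.4f, converged = %s\n",
                object@iterations, object@logLik, object@converged))
})

setMethod("show", "BackgroundModel", function(object) {
    cat(sprintf(
        "BackgroundModel: NB(size = %.4g, prob = %.4g), uniform on [%d, %d], eps = %g\n",
        object@size, object@prob, object@tMin, object@tMax, object@eps))
})

setMethod("show", "PriorModel", function(object) {
    cat(sprintf(
        "PriorModel: pi = %.4g (fdr = %.3g, peak length = %.4g bp, effective genome = %.4g bp)\n",
        object@pi, object@fdr, object@peakLength, object@genomeLength))
})
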