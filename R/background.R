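#' Moment estimator for the negative-binomial background
#'
#' Fits the NB size/prob parameters to background window total counts by the
#' method of moments. With sample mean \code{m} and sample variance
#' \code{s2}, the NB with mean \code{r(1-p)/p} and variance \code{r(1-p)/p^2}
#' gives \code{p = m/s2} and \code{r = m^2/(s2 - m)}. When the sample shows
#' no overdispersion (\code{s2 <= m}) the estimator is undefined; the fit
#' falls back to a quasi-Poisson limit (very large size at the same mean)
#' with a warning.
#'
#' @param totals background window totals (numeric vector, or the
#'   \code{GRanges} returned by [harvestBackgroundWindows()]).
#' @return named numeric vector \code{c(size, prob)}.
#' @examples
#' fitNBMoments(c(3, 7, 1, 9, 5))   # mean 5, var 10 -> size 5, prob 0.5
#' @export
fitNBMoments <- function(totals) {
    if (is(totals, "GRanges")) totals <- mcols(totals)$total
    totals <- as.numeric(totals)
    if (length(totals) < 2L)
        stop("need at least 2 background windows", call. = FALSE)
    m <- mean(totals)
    s2 <- var(totals)
    if (m <= 0)
        stop("background windows have zero mean count", call. = FALSE)
    if (s2 <= m) {
        warning("background counts not overdispersed (s2 <= mean); ",
                "using quasi-Poisson fallback", call. = FALSE)
        r <- 1e6 * m
        return(c(size = r, prob = r / (r + m)))
    }
    c(size = m^2 / (s2 - m), prob = m / s2)
}

#' Support bounds of the uniform total-count component
#'
#' The binding-state total count is modelled as discrete uniform on
#' \code{[a, b]} where \code{a} and \code{b} are the minimum and maximum
#' total count over all candidate peaks.
#'
#' @param peakTotals total counts of all candidate peaks.
#' @return named numeric vector \code{c(tMin, tMax)}.
#' @export
uniformBounds <- function(peakTotals) {
    peakTotals <- as.numeric(peakTotals)
    if (length(peakTotals) == 0L)
        stop("empty candidate peak list", call. = FALSE)
    c(tMin = min(peakTotals), tMax = max(peakTotals))
}

#' Fit the full background total-count model
#'
#' Convenience constructor combining [fitNBMoments()] on the background
#' windows with [uniformBounds()] on the candidate peak totals.
#'
#' @param bgTotals background window totals (vector or \code{GRanges}).
#' @param peakTotals candidate peak total counts.
#' @param eps outlier mixing weight (default 0.001, fixed).
#' @return a \linkS4class{BackgroundModel}.
#' @export
fitBackgroundModel <- function(bgTotals, peakTotals, eps = 0.001) {
    nb <- fitNBMoments(bgTotals)
    ab <- uniformBounds(peakTotals)
    new("BackgroundModel", size = unname(nb["size"]),
        prob = unname(nb["prob"]), tMin = unname(ab["tMin"]),
        tMax = unname(ab["tMax"]), eps = eps)
}

## log of the discrete uniform mass on [tMin, tMax]; -Inf off support
.logUnif <- function(T, model) {
    ifelse(T >= model@tMin & T <= model@tMax,
           -log(model@tMax - model@tMin + 1), -Inf)
}

#' Background log-density of the total count
#'
#' \code{log[(1-eps) NB(T; size, prob) + eps U(T; tMin, tMax)]}, with the
#' discrete uniform mass \code{1/(tMax-tMin+1)} on its support and zero
#' outside. Evaluated in log space so it stays finite for totals up to 1e7
#' wherever either component has mass.
#'
#' @param T non-negative total count (vectorised).
#' @param model a \linkS4class{BackgroundModel}.
#' @return log density (vectorised).
#' @export
logF0 <- function(T, model) {
    stopifnot(is(model, "BackgroundModel"), all(T >= 0))
    lnb <- dnbinom(T, size = model@size, prob = model@prob, log = TRUE)
    lu <- .logUnif(T, model)
    if (model@eps <= 0) return(lnb)
    if (model@eps >= 1) return(lu)
    .logSumExp(log1p(-model@eps) + lnb, log(model@eps) + lu)
}

#' Binding log-density of the total count
#'
#' \code{log U(T; tMin, tMax)}: the discrete uniform on the observed range of
#' candidate totals; \code{-Inf} outside. Together with [logF0()] this makes
#' the total-count likelihood ratio increase monotonically with T on the
#' support while staying bounded at \code{1/eps}, so outlier-rich artifact
#' windows cannot dominate the ranking on count alone.
#'
#' @inheritParams logF0
#' @return log density (vectorised).
#' @export
logF1 <- function(T, model) {
    stopifnot(is(model, "BackgroundModel"), all(T >= 0))
    .logUnif(T, model)
}
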