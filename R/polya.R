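#' Log pmf of the multivariate Polya (Dirichlet-multinomial) distribution
#'
#' The marginal distribution of multinomial counts whose probability vector
#' is Dirichlet(alpha)-distributed:
#' \deqn{P(x) = \frac{T!}{\prod_j x_j!}\,
#'   \frac{\Gamma(|\alpha|)}{\Gamma(T+|\alpha|)}
#'   \prod_j \frac{\Gamma(x_j+\alpha_j)}{\Gamma(\alpha_j)},}
#' with \eqn{T = \sum_j x_j} and \eqn{|\alpha| = \sum_j \alpha_j}. It
#' generalizes the Beta-binomial and models overdispersed bin counts: the
#' mean shape is \eqn{\alpha/|\alpha|} and smaller \eqn{|\alpha|} allows more
#' peak-to-peak shape variability. Computed with log-gamma arithmetic, so it
#' is finite and stable for large counts.
#'
#' @param x non-negative integer counts: a vector of length K or a matrix
#'   with K columns (one row per observation).
#' @param params a \linkS4class{PolyaParams} or positive numeric vector
#'   alpha of length K.
#' @return log probability; one value per row of \code{x}.
#' @examples
#' # Beta-binomial(1,1) is uniform: P{(k, n-k)} = 1/(n+1)
#' exp(logDirichletMultinomial(c(3, 2), c(1, 1)))  # 1/6
#' @export
logDirichletMultinomial <- function(x, params) {
    a <- if (is(params, "PolyaParams")) params@alpha else as.numeric(params)
    if (any(a <= 0)) stop("alpha entries must be > 0", call. = FALSE)
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    if (ncol(x) != length(a))
        stop(sprintf("dimension mismatch: %d count slots vs %d alpha entries",
                     ncol(x), length(a)), call. = FALSE)
    if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
    A <- sum(a)
    T <- rowSums(x)
    lgamma(T + 1) - rowSums(lgamma(x + 1)) +
        lgamma(A) - lgamma(T + A) +
        rowSums(lgamma(sweep(x, 2L, a, "+"))) - sum(lgamma(a))
}

## moment-based initial alpha: normalized category means with a concentration
## matched to the mean within-vector overdispersion; all-ones shape fallback
.momentInit <- function(x, active) {
    T <- rowSums(x)
    use <- T > 0
    pbar <- colSums(x[use, , drop = FALSE]) / sum(x[use, ])
    P <- x[use, , drop = FALSE] / T[use]
    vj <- apply(P, 2L, var)
    pq <- pbar * (1 - pbar)
    c1 <- mean(1 / T[use])
    c2 <- mean((T[use] - 1) / T[use])
    # under the model, var(P_j) ~ p(1-p) * (c1 + c2/(A+1))
    rho <- (sum(vj) - c1 * sum(pq)) / (c2 * sum(pq))
    A0 <- if (is.finite(rho) && rho > 0 && rho < 1) 1 / rho - 1
          else length(pbar)
    a0 <- pbar * A0
    a0[!active | a0 <= 0] <- 1e-6
    a0
}

#' Maximum-likelihood Polya parameters by the MM algorithm
#'
#' Fits the Dirichlet-multinomial parameter vector alpha to a set of count
#' vectors by Minorization-Maximization. Each iteration applies the
#' multiplicative update
#' \deqn{\alpha_j \leftarrow \alpha_j \,
#'   \frac{\sum_i [\psi(\alpha_j + x_{ij}) - \psi(\alpha_j)]}
#'        {\sum_i [\psi(|\alpha| + T_i) - \psi(|\alpha|)]},}
#' where the digamma differences equal the inner sums
#' \eqn{\sum_{k=0}^{x-1} 1/(\alpha+k)} exactly for integer counts. The MM
#' construction guarantees a non-decreasing log-likelihood at every step.
#' Categories with zero total count across all observations are floored at
#' 1e-6 and frozen. When the data are under-dispersed (near-multinomial) the
#' MLE diverges towards infinite concentration; the fit then stops at the
#' iteration cap with \code{converged = FALSE} and a still-monotone trace.
#'
#' @param x a \linkS4class{PeakBinCounts} or a non-negative integer matrix
#'   (observations in rows).
#' @param init \code{"moment"} (default) for a moment-matched start, or a
#'   positive numeric vector / \linkS4class{PolyaParams} start.
#' @param tol convergence tolerance on the relative log-likelihood change
#'   (default 1e-8).
#' @param maxIter iteration cap (default 1000).
#' @return a \linkS4class{PolyaFit}.
#' @export
fitPolyaMM <- function(x, init = "moment", tol = 1e-8, maxIter = 1000L) {
    if (is(x, "PeakBinCounts")) x <- binCounts(x)
    x <- as.matrix(x)
    if (any(x < 0) || any(x != round(x)))
        stop("counts must be non-negative integers", call. = FALSE)
    n <- nrow(x); K <- ncol(x)
    T <- rowSums(x)
    if (all(T == 0))
        stop("all observations have zero total count", call. = FALSE)
    active <- colSums(x) > 0

    if (is(init, "PolyaParams")) init <- init@alpha
    if (is.character(init) && identical(init, "moment")) {
        a <- .momentInit(x, active)
    } else {
        a <- as.numeric(init)
        if (length(a) != K || any(a <= 0))
            stop("init must be a positive vector of length K", call. = FALSE)
        a[!active] <- 1e-6
    }

    # sparse triplets: only nonzero counts contribute to the sums
    nz <- which(x > 0, arr.ind = TRUE)
    nzi <- nz[, 1L]; nzj <- nz[, 2L]; nzx <- x[nz]
    # multinomial coefficient, constant across iterations
    constCoef <- sum(lgamma(T + 1)) - sum(lgamma(nzx + 1))
    tTab <- table(T[T > 0])
    tVal <- as.numeric(names(tTab)); tCnt <- as.numeric(tTab)
    nPos <- sum(tCnt)

    loglikOf <- function(a) {
        A <- sum(a)
        constCoef + nPos * lgamma(A) - sum(tCnt * lgamma(tVal + A)) +
            sum(lgamma(nzx + a[nzj]) - lgamma(a[nzj]))
    }

    ll <- loglikOf(a)
    trace <- ll
    converged <- FALSE
    iter <- 0L
    jIdx <- sort(unique(nzj))
    while (iter < maxIter) {
        iter <- iter + 1L
        A <- sum(a)
        num <- numeric(K)
        contrib <- digamma(a[nzj] + nzx) - digamma(a[nzj])
        num[jIdx] <- rowsum(contrib, nzj)[, 1L]
        den <- sum(tCnt * digamma(tVal + A)) - nPos * digamma(A)
        upd <- active & num > 0
        a[upd] <- a[upd] * num[upd] / den
        a[a < 1e-6] <- 1e-6
        llNew <- loglikOf(a)
        trace <- c(trace, llNew)
        if (is.finite(llNew) && is.finite(ll) &&
            abs(llNew - ll) <= tol * (abs(ll) + 1e-10)) {
            converged <- TRUE
            ll <- llNew
            break
        }
        if (!is.finite(llNew))
            stop("non-finite log-likelihood in MM fit (iteration ", iter,
                 "); check the input counts", call. = FALSE)
        ll <- llNew
    }
    names(a) <- colnames(x)
    new("PolyaFit", alpha = a, iterations = iter, logLik = ll,
        trace = trace, converged = converged)
}

#' Estimate the background shape parameters
#'
#' Fits the background Dirichlet parameter vector on bin-count vectors of
#' randomly sampled non-peak intervals (see [sampleBackgroundIntervals()]).
#'
#' @param bgVectors a \linkS4class{PeakBinCounts} of background intervals.
#' @param tol,maxIter passed to [fitPolyaMM()].
#' @return a \linkS4class{PolyaFit} (alpha0).
#' @export
estimateAlpha0 <- function(bgVectors, tol = 1e-8, maxIter = 1000L) {
    fitPolyaMM(bgVectors, init = "moment", tol = tol, maxIter = maxIter)
}

#' Estimate the binding shape parameters from top-ranked peaks
#'
#' The top \code{n1} candidates by first-step source rank are taken as
#' high-confidence binding sites and used as training data for the binding
#' shape alpha1. Peaks flagged shape-unusable (truncated windows) are
#' excluded from training.
#'
#' @param counts a \linkS4class{PeakBinCounts} of all candidate peaks.
#' @param sourceRank integer vector of first-step ranks (1 = best), parallel
#'   to the rows of \code{counts}.
#' @param n1 number of top peaks to train on (default 2000). If fewer
#'   candidates exist, all are used with a warning.
#' @param tol,maxIter passed to [fitPolyaMM()].
#' @return a \linkS4class{PolyaFit} (alpha1).
#' @export
estimateAlpha1 <- function(counts, sourceRank, n1 = 2000L, tol = 1e-8,
                           maxIter = 1000L) {
    stopifnot(is(counts, "PeakBinCounts"))
    n <- nrow(binCounts(counts))
    if (length(sourceRank) != n)
        stop("sourceRank must be parallel to the count rows", call. = FALSE)
    if (n1 > n) {
        warning("n1 = ", n1, " exceeds the ", n,
                " candidate peaks; training on all of them", call. = FALSE)
        n1 <- n
    }
    sel <- sourceRank <= n1 & shapeUsable(counts)
    if (!any(sel))
        stop("no shape-usable training peaks", call. = FALSE)
    fitPolyaMM(counts[which(sel)], init = "moment", tol = tol,
               maxIter = maxIter)
}
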