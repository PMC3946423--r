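suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

## Independent Dirichlet-multinomial pmf oracle: the Gamma-ratio formula
## written out as a product of rational factors (no log-gamma), exact up to
## double rounding for small counts.
dmOracle <- function(x, a) {
    T <- sum(x)
    A <- sum(a)
    coef <- factorial(T) / prod(factorial(x))
    num <- prod(unlist(lapply(seq_along(x), function(j)
        if (x[j] == 0) 1 else a[j] + 0:(x[j] - 1))))
    den <- if (T == 0) 1 else prod(A + 0:(T - 1))
    coef * num / den
}

## Independent log-gamma NB pmf (cross-check for dnbinom-based logF0)
nbLogPmfOracle <- function(x, size, prob) {
    lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
        size * log(prob) + x * log(1 - prob)
}

## all compositions of T into K non-negative parts
compositions <- function(T, K) {
    if (K == 1L) return(matrix(T, 1L, 1L))
    do.call(rbind, lapply(0:T, function(k)
        cbind(k, compositions(T - k, K - 1L), deparse.level = 0)))
}

## seeded Dirichlet-multinomial sampler (simulation oracle for MM recovery)
rDirMult <- function(n, alpha, size) {
    t(vapply(seq_len(n), function(i) {
        g <- rgamma(length(alpha), shape = alpha)
        rmultinom(1L, size, g / sum(g))[, 1L]
    }, integer(length(alpha))))
}

## tiny stranded read GRanges builder (1-based inclusive coords)
mkReads <- function(chrom, start1, width, strand) {
    GRanges(chrom, IRanges(start1, width = width), strand = strand)
}

## peak GRanges with summit/id/sourceRank metadata
mkPeaks <- function(chrom, summit1, half = 200L, ids = NULL, ranks = NULL) {
    n <- length(summit1)
    gr <- GRanges(chrom, IRanges(summit1 - half, summit1 + half - 1L))
    mcols(gr) <- DataFrame(
        summit = as.integer(summit1),
        sourceRank = if (is.null(ranks)) seq_len(n) else ranks,
        sourceScore = rep(NA_real_, n),
        id = if (is.null(ids)) sprintf("p%02d", seq_len(n)) else ids)
    gr
}

## the MM-trace monotonicity check used across tests
expectMonotoneTrace <- function(fit, tol = 1e-8) {
    tr <- fit@trace
    expect_true(all(diff(tr) >= -tol * (abs(tr[-length(tr)]) + 1)))
}
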