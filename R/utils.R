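## run code under a fixed RNG seed, restoring the caller's RNG state after
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

## pool one or more GRanges of reads (replicates) into a single GRanges
.poolReads <- function(reads, what = "reads") {
    if (is(reads, "GRanges")) return(reads)
    if (is.list(reads) || is(reads, "GRangesList")) {
        if (length(reads) == 0L)
            stop("empty ", what, " list", call. = FALSE)
        return(do.call(c, lapply(reads, function(g) {
            if (!is(g, "GRanges"))
                stop(what, " must be GRanges or a list of GRanges",
                     call. = FALSE)
            g
        })))
    }
    stop(what, " must be GRanges or a list of GRanges", call. = FALSE)
}

## 0-based 5'-most aligned base of each read: start for +, end-1 for -
.fivePrime0 <- function(reads) {
    s <- as.character(GenomicRanges::strand(reads))
    if (any(s == "*"))
        stop("reads must be stranded (+/-)", call. = FALSE)
    ifelse(s == "+", GenomicRanges::start(reads) - 1L,
           GenomicRanges::end(reads) - 1L)
}

.logSumExp <- function(a, b) {
    m <- pmax(a, b)
    r <- m + log(exp(a - m) + exp(b - m))
    r[a == -Inf & b == -Inf] <- -Inf
    r
}
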