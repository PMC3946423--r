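#' Simulation configuration
#'
#' Builds the parameter list for [simulateChipSeq()]. The defaults emulate a
#' transcription-factor ChIP-seq experiment at desk scale: a single synthetic
#' chromosome; true binding sites emitting strand-shifted bimodal read
#' clouds whose per-site bin proportions are Dirichlet-distributed around a
#' canonical template; artifact sites with the same total-count distribution
#' but single-strand spike shapes; and negative-binomial background window
#' counts.
#'
#' @param chromName,chromLength the synthetic chromosome.
#' @param nTrueSites,nArtifactSites,nBackgroundCandidates numbers of true
#'   binding sites, shape-artifact sites, and background windows added to
#'   the candidate list as decoys.
#' @param fragmentOffset distance in bp between the forward- and
#'   reverse-strand mode centres (the fragment-length shift).
#' @param shapeConcentration Dirichlet concentration of per-site shape
#'   variability; larger = more similar peaks.
#' @param backgroundNB \code{c(size, prob)} of the NB window-count law.
#' @param readsPerSite \code{c(size, mu)} of the NB law for per-site read
#'   totals (shared by true and artifact sites, so totals are matched).
#' @param ipEnrichment ratio of IP to control reads at sites.
#' @param readLength read length in bp.
#' @param window,bin binning geometry the data are designed for.
#' @param summitJitter max absolute uniform jitter (bp) of reported summits.
#' @param seed RNG seed.
#' @return a named list (class \code{simConfig}).
#' @export
simConfig <- function(chromName = "chrS", chromLength = 4e6,
                      nTrueSites = 500L, nArtifactSites = 500L,
                      nBackgroundCandidates = 200L,
                      fragmentOffset = 160L, shapeConcentration = 60,
                      backgroundNB = c(size = 5, prob = 0.5),
                      readsPerSite = c(size = 10, mu = 120),
                      ipEnrichment = 5, readLength = 36L,
                      window = 800L, bin = 10L, summitJitter = 20L,
                      seed = 1L) {
    cfg <- list(chromName = chromName, chromLength = as.numeric(chromLength),
                nTrueSites = as.integer(nTrueSites),
                nArtifactSites = as.integer(nArtifactSites),
                nBackgroundCandidates = as.integer(nBackgroundCandidates),
                fragmentOffset = as.integer(fragmentOffset),
                shapeConcentration = shapeConcentration,
                backgroundNB = backgroundNB, readsPerSite = readsPerSite,
                ipEnrichment = ipEnrichment,
                readLength = as.integer(readLength),
                window = as.integer(window), bin = as.integer(bin),
                summitJitter = as.integer(summitJitter),
                seed = as.integer(seed))
    stopifnot(cfg$nTrueSites >= 0L, cfg$nArtifactSites >= 0L,
              cfg$fragmentOffset >= 0L, cfg$shapeConcentration > 0,
              cfg$window %% cfg$bin == 0L, cfg$window %% 2L == 0L)
    class(cfg) <- "simConfig"
    cfg
}

## canonical bimodal slot template: two mirrored triangular lobes offset by
## the fragment shift in the IP slots, flat control slots
.bimodalTemplate <- function(m, offsetBins, ipEnrichment, halfWidth = 6) {
    tri <- function(center) pmax(0, 1 - abs(seq_len(m) - 1 - center) /
                                        halfWidth)
    cF <- (m - 1) / 2 - offsetBins / 2
    cR <- (m - 1) / 2 + offsetBins / 2
    ipShare <- ipEnrichment / (ipEnrichment + 1)
    lobeF <- tri(cF); lobeR <- tri(cR)
    lobes <- c(lobeF / sum(lobeF), lobeR / sum(lobeR)) / 2
    ip <- 0.9 * lobes + 0.1 / (2 * m)
    ctrl <- rep(1 / (2 * m), 2 * m)
    c(ip * ipShare, ctrl * (1 - ipShare))
}

## artifact slot template: all IP mass on one strand in <=3 adjacent bins
.artifactTemplate <- function(m, spikeBin, spikeStrand, ipEnrichment) {
    ipShare <- ipEnrichment / (ipEnrichment + 1)
    strandVec <- numeric(m)
    bins <- intersect(spikeBin + 0:2, seq_len(m))
    strandVec[bins] <- 1 / length(bins)
    ip <- if (spikeStrand == 1L) c(strandVec, numeric(m))
          else c(numeric(m), strandVec)
    ip <- 0.95 * ip + 0.05 / (2 * m)
    ctrl <- rep(1 / (2 * m), 2 * m)
    c(ip * ipShare, ctrl * (1 - ipShare))
}

.rdirichlet1 <- function(a) {
    g <- rgamma(length(a), shape = a, rate = 1)
    if (sum(g) <= 0) g[which.max(a)] <- 1
    g / sum(g)
}

#' Simulate a strand-resolved ChIP-seq dataset with known truth
#'
#' Generates IP and control reads, a candidate peak list and a truth table
#' under the generative hierarchy the scoring model assumes. True sites emit
#' forward reads centred half a fragment upstream and reverse reads half a
#' fragment downstream of the site, with per-site multinomial bin
#' proportions drawn from a Dirichlet around the canonical bimodal template.
#' Artifact sites draw their totals from the same law (matched counts) but
#' place essentially all IP reads on one strand in at most three bins.
#' Background reads are scattered with NB window totals. The candidate list
#' contains every true and artifact site (summit jittered up to
#' \code{summitJitter} bp) plus sampled background windows, with the
#' first-step signal taken as the IP read count near the summit.
#'
#' @param cfg a [simConfig()].
#' @return a list with elements \code{ip}, \code{control} (read
#'   \code{GRanges}), \code{peaks} (candidate \code{GRanges} with
#'   \code{summit}, \code{sourceScore}, \code{sourceRank}, \code{id}),
#'   \code{truth} (\code{data.frame}: id, class, center, readsEmitted),
#'   \code{chromLengths}, and \code{config}.
#' @export
simulateChipSeq <- function(cfg = simConfig()) {
    stopifnot(inherits(cfg, "simConfig"))
    .withSeed(cfg$seed, .simulateChipSeqImpl(cfg))
}

.simulateChipSeqImpl <- function(cfg) {
    w <- cfg$window; b <- cfg$bin; m <- w %/% b
    K <- m * 2L * 2L
    L <- cfg$chromLength
    nSites <- cfg$nTrueSites + cfg$nArtifactSites
    margin <- w + cfg$summitJitter + cfg$readLength
    minGap <- w + 2L * cfg$summitJitter

    ## place site centres by rejection: redraw clashing sites, cap 100 rounds
    centers <- sort(round(runif(nSites, margin, L - margin)))
    if (nSites > 1L) {
        for (round in seq_len(100L)) {
            gap <- diff(centers)
            bad <- which(gap < minGap) + 1L
            if (length(bad) == 0L) break
            if (round == 100L)
                stop("could not place non-overlapping sites after 100 ",
                     "redraws; reduce site count or enlarge the chromosome",
                     call. = FALSE)
            centers[bad] <- round(runif(length(bad), margin, L - margin))
            centers <- sort(centers)
        }
    }
    classes <- rep(c("true_site", "artifact"),
                   c(cfg$nTrueSites, cfg$nArtifactSites))
    if (nSites > 0L)
        classes <- classes[sample.int(nSites)]  # interleave classes

    offsetBins <- cfg$fragmentOffset / b
    trueTpl <- .bimodalTemplate(m, offsetBins, cfg$ipEnrichment)
    siteCounts <- matrix(0L, nrow = nSites, ncol = K)
    totals <- if (nSites > 0L)
        rnbinom(nSites, size = cfg$readsPerSite[["size"]],
                mu = cfg$readsPerSite[["mu"]]) else integer()
    for (i in seq_len(nSites)) {
        tpl <- if (classes[i] == "true_site") trueTpl
        else .artifactTemplate(m,
                spikeBin = sample(seq(m %/% 2L - 10L, m %/% 2L + 10L), 1L),
                spikeStrand = sample(1:2, 1L),
                ipEnrichment = cfg$ipEnrichment)
        p <- .rdirichlet1(cfg$shapeConcentration * tpl)
        if (totals[i] > 0L)
            siteCounts[i, ] <- rmultinom(1L, totals[i], p)[, 1L]
    }

    ## expand slot counts into read 5' positions
    readChrom <- cfg$chromName
    emit <- function(rows) {
        idx <- which(siteCounts[rows, , drop = FALSE] > 0, arr.ind = TRUE)
        if (nrow(idx) == 0L)
            return(list(pos0 = integer(), strand = character(),
                        sample = integer()))
        siteRow <- rows[idx[, 1L]]
        col0 <- idx[, 2L] - 1L
        cnt <- siteCounts[rows, , drop = FALSE][idx]
        s <- col0 %/% (2L * m) + 1L          # 1 = IP, 2 = control
        st <- (col0 %/% m) %% 2L + 1L        # 1 = fwd, 2 = rev
        bin0 <- col0 %% m
        n <- sum(cnt)
        rp <- function(v) rep(v, cnt)
        winStart0 <- rp(centers[siteRow]) - w %/% 2L
        pos0 <- winStart0 + rp(bin0) * b + floor(runif(n) * b)
        list(pos0 = as.integer(pos0), strand = c("+", "-")[rp(st)],
             sample = rp(s))
    }
    siteReads <- emit(seq_len(nSites))

    ## background: NB totals in non-site windows tiled across the chromosome
    nw <- floor(L / w)
    winStart0 <- (seq_len(nw) - 1L) * w
    nearSite <- rep(FALSE, nw)
    if (nSites > 0L) {
        for (i in seq_len(nSites)) {
            lo <- max(1L, floor((centers[i] - w) / w) + 1L)
            hi <- min(nw, floor((centers[i] + w) / w) + 1L)
            nearSite[lo:hi] <- TRUE
        }
    }
    ## background covers the whole chromosome (sites sit on top of it);
    ## site-free windows are tracked only to place decoy candidates
    bgIdx <- seq_len(nw)
    bgTot <- rnbinom(length(bgIdx), size = cfg$backgroundNB[["size"]],
                     prob = cfg$backgroundNB[["prob"]])
    nBg <- sum(bgTot)
    bgWin <- rep(bgIdx, bgTot)
    bgPos0 <- as.integer(winStart0[bgWin] + floor(runif(nBg) * w))
    bgStrand <- c("+", "-")[1L + (runif(nBg) < 0.5)]
    bgSample <- 1L + (runif(nBg) < 0.5)      # IP / control equally

    pos0 <- c(siteReads$pos0, bgPos0)
    strandChr <- c(siteReads$strand, bgStrand)
    sampleId <- c(siteReads$sample, bgSample)
    RL <- cfg$readLength
    readStart0 <- ifelse(strandChr == "+", pos0, pos0 - RL + 1L)
    readStart0 <- pmax(readStart0, 0L)
    mkReads <- function(which) {
        idx <- which(which)
        GRanges(rep(readChrom, length(idx)),
                IRanges(readStart0[idx] + 1L, width = RL),
                strand = strandChr[idx])
    }
    ip <- mkReads(sampleId == 1L)
    control <- mkReads(sampleId == 2L)

    ## candidate peaks: sites (jittered summits) + background decoys
    jit <- if (nSites > 0L)
        sample(seq(-cfg$summitJitter, cfg$summitJitter), nSites,
               replace = TRUE) else integer()
    summit0 <- centers + jit
    ids <- sprintf("site_%04d", seq_len(nSites))
    farIdx <- which(!nearSite)
    nBgCand <- min(cfg$nBackgroundCandidates, length(farIdx))
    bgCand <- if (nBgCand > 0L) sort(sample(farIdx, nBgCand)) else integer()
    bgSummit0 <- as.integer(winStart0[bgCand] + w %/% 2L)
    candSummit0 <- c(summit0, bgSummit0)
    candIds <- c(ids, sprintf("bgcand_%04d", seq_len(nBgCand)))
    candClass <- c(classes, rep("background", nBgCand))
    ## candidate intervals are narrower than the scoring window, as with a
    ## real first-step caller; peak flanks therefore remain in the "non-peak"
    ## territory, as they do in real data
    halfPeak <- 200L
    nCand <- length(candSummit0)
    peaks <- GRanges(rep(readChrom, nCand),
                     IRanges(candSummit0 - halfPeak + 1L,
                             candSummit0 + halfPeak))
    ## first-step signal: IP reads with 5' base within +/- w/2 of the summit
    ip5 <- .fivePrime0(ip)
    sig <- countOverlaps(
        GRanges(rep(readChrom, nCand),
                IRanges(candSummit0 - w %/% 2L + 1L,
                        candSummit0 + w %/% 2L)),
        GRanges(rep(readChrom, length(ip5)),
                IRanges(ip5 + 1L, width = 1L)),
        ignore.strand = TRUE)
    sourceRank <- integer(length(sig))
    sourceRank[order(-sig)] <- seq_along(sig)
    mcols(peaks) <- DataFrame(summit = candSummit0 + 1L,
                              sourceRank = sourceRank,
                              sourceScore = as.numeric(sig), id = candIds)
    truth <- data.frame(
        id = candIds, class = candClass,
        center = c(centers + 1, bgSummit0 + 1),
        readsEmitted = c(as.integer(rowSums(siteCounts)),
                         bgTot[match(bgCand, bgIdx)]),
        stringsAsFactors = FALSE)
    chromLengths <- stats::setNames(L, readChrom)
    list(ip = ip, control = control, peaks = peaks, truth = truth,
         chromLengths = chromLengths, config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Writes \code{ip.bed}, \code{control.bed} (BED6),
#' \code{peaks.narrowPeak}, \code{truth.tsv} and \code{chrom.sizes} into
#' \code{dir}.
#'
#' @param sim output of [simulateChipSeq()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named vector of the file paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(ip = file.path(dir, "ip.bed"),
               control = file.path(dir, "control.bed"),
               peaks = file.path(dir, "peaks.narrowPeak"),
               truth = file.path(dir, "truth.tsv"),
               chromSizes = file.path(dir, "chrom.sizes"))
    writeBedReads(sim$ip, paths[["ip"]])
    writeBedReads(sim$control, paths[["control"]])
    writeNarrowPeak(sim$peaks, paths[["peaks"]])
    data.table::fwrite(sim$truth, paths[["truth"]], sep = "\t",
                       quote = FALSE)
    writeLines(sprintf("%s\t%d", names(sim$chromLengths),
                       as.integer(sim$chromLengths)),
               paths[["chromSizes"]])
    invisible(paths)
}

#' Evaluate a ranking against the simulation truth
#'
#' Computes the AUC (by rank-sum) for separating a positive truth class from
#' negative classes, and the fraction of positives among the top-k ranked
#' peaks over a grid of k.
#'
#' @param rankedIds peak ids in ranked order (best first), e.g.
#'   \code{mcols(ranked)$id} from [rankPeaks()].
#' @param truth the simulator truth table.
#' @param positive truth class treated as positive (default
#'   \code{"true_site"}).
#' @param negative truth classes treated as negative (default: all others
#'   present).
#' @param kGrid grid for the top-k fractions.
#' @return list with \code{auc}, \code{topK} (named fraction vector),
#'   \code{nPositive}, \code{nNegative}.
#' @export
evaluateRanking <- function(rankedIds, truth, positive = "true_site",
                            negative = NULL,
                            kGrid = c(100L, 200L, 500L, 1000L)) {
    unknown <- setdiff(rankedIds, truth$id)
    if (length(unknown))
        stop("ranked ids not present in the truth table: ",
             paste(head(unknown, 3L), collapse = ", "), call. = FALSE)
    cls <- truth$class[match(rankedIds, truth$id)]
    if (is.null(negative)) negative <- setdiff(unique(cls), positive)
    keep <- cls %in% c(positive, negative)
    pos <- which(cls[keep] == positive)      # rank positions, 1 = best
    neg <- which(cls[keep] %in% negative)
    if (length(pos) == 0L || length(neg) == 0L)
        stop("need at least one positive and one negative peak",
             call. = FALSE)
    # AUC = P(positive ranked above negative); smaller position is better
    r <- rank(-c(pos, neg))
    auc <- (sum(r[seq_along(pos)]) -
            length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
    topK <- vapply(kGrid, function(k) {
        k <- min(k, length(cls))
        mean(cls[seq_len(k)] == positive)
    }, numeric(1))
    names(topK) <- paste0("top", pmin(kGrid, length(cls)))
    list(auc = auc, topK = topK, nPositive = length(pos),
         nNegative = length(neg))
}
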