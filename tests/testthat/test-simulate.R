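smallCfg <- function(...) simConfig(chromLength = 6e5, nTrueSites = 40L,
                                    nArtifactSites = 20L,
                                    nBackgroundCandidates = 10L, ...)

test_that("simulation is byte-identical under a fixed seed", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    runSimulation(d1, smallCfg(seed = 9L))
    runSimulation(d2, smallCfg(seed = 9L))
    for (f in list.files(d1))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = f)
})

test_that("class structure of the candidate list matches the config", {
    sim <- simulateChipSeq(smallCfg(seed = 2L))
    expect_equal(length(sim$peaks), 40L + 20L + 10L)
    expect_equal(nrow(sim$truth), length(sim$peaks))
    expect_equal(sum(sim$truth$class == "true_site"), 40L)
    expect_equal(sum(sim$truth$class == "artifact"), 20L)
    expect_setequal(mcols(sim$peaks)$sourceRank, seq_along(sim$peaks))
    # with artifacts and background candidates off, every candidate is true
    pure <- simulateChipSeq(simConfig(chromLength = 4e5, nTrueSites = 25L,
                                      nArtifactSites = 0L,
                                      nBackgroundCandidates = 0L, seed = 3L))
    expect_true(all(pure$truth$class == "true_site"))
})

test_that("with background off, emitted reads match the truth table", {
    cfg <- simConfig(chromLength = 4e5, nTrueSites = 30L,
                     nArtifactSites = 10L, nBackgroundCandidates = 0L,
                     backgroundNB = c(size = 5, prob = 1), seed = 6L)
    sim <- simulateChipSeq(cfg)
    expect_equal(length(sim$ip) + length(sim$control),
                 sum(sim$truth$readsEmitted))
})

test_that("true sites show the forward/reverse strand offset", {
    sim <- simulateChipSeq(simConfig(chromLength = 8e5, nTrueSites = 60L,
                                     nArtifactSites = 0L,
                                     nBackgroundCandidates = 0L,
                                     backgroundNB = c(size = 5, prob = 1),
                                     seed = 12L))
    truth <- sim$truth
    p0 <- ifelse(as.character(strand(sim$ip)) == "+",
                 start(sim$ip) - 1L, end(sim$ip) - 1L)
    # assign reads to the nearest site centre
    centers <- truth$center - 1L
    nearest <- centers[max.col(-abs(outer(p0, centers, "-")))]
    fwd <- as.character(strand(sim$ip)) == "+"
    offF <- mean((p0 - nearest)[fwd])
    offR <- mean((p0 - nearest)[!fwd])
    expect_lt(offF, 0)       # forward cloud upstream of the centre
    expect_gt(offR, 0)       # reverse cloud downstream
    expect_equal(offR - offF, sim$config$fragmentOffset, tolerance = 0.2)
})

test_that("background window counts match the configured NB law", {
    cfg <- simConfig(chromLength = 8e6, nTrueSites = 0L,
                     nArtifactSites = 0L, nBackgroundCandidates = 0L,
                     backgroundNB = c(size = 5, prob = 0.5), seed = 20L)
    sim <- simulateChipSeq(cfg)
    reads <- c(sim$ip, sim$control)
    p0 <- ifelse(as.character(strand(reads)) == "+",
                 start(reads) - 1L, end(reads) - 1L)
    w <- cfg$window
    tot <- tabulate(p0 %/% w + 1L, nbins = floor(cfg$chromLength / w))
    # chi-square GOF against NB(5, 0.5), tail bins pooled to expected >= 5
    n <- length(tot)
    maxc <- max(tot)
    pr <- dnbinom(0:maxc, size = 5, prob = 0.5)
    obs <- tabulate(tot + 1L, nbins = maxc + 1L)
    cut <- max(which(pr * n >= 5))
    obsP <- c(obs[1:cut], sum(obs[-(1:cut)]))
    prP <- c(pr[1:cut], 1 - sum(pr[1:cut]))
    pval <- chisq.test(obsP, p = prP)$p.value
    expect_gt(pval, 0.01)
})

test_that("ranking evaluation: perfect, reversed, and random orders", {
    truth <- data.frame(id = sprintf("x%03d", 1:100),
                        class = rep(c("true_site", "artifact"), each = 50),
                        center = 1:100, readsEmitted = 1)
    perfect <- truth$id                      # positives first
    expect_equal(evaluateRanking(perfect, truth)$auc, 1)
    expect_equal(evaluateRanking(rev(perfect), truth)$auc, 0)
    ev <- evaluateRanking(perfect, truth, kGrid = c(25L, 80L))
    expect_equal(unname(ev$topK), c(1, 50 / 80))
    # random rankings of 500+500 hover at 0.5 (permutation sampling)
    bigTruth <- data.frame(id = sprintf("y%04d", 1:1000),
                           class = rep(c("true_site", "artifact"),
                                       each = 500),
                           center = 1:1000, readsEmitted = 1)
    set.seed(4)
    aucs <- replicate(20, evaluateRanking(sample(bigTruth$id), bigTruth)$auc)
    expect_true(all(abs(aucs - 0.5) < 0.06))
    expect_lt(abs(mean(aucs) - 0.5), 0.02)
    expect_error(evaluateRanking(c("nope", bigTruth$id), bigTruth),
                 "not present")
})
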