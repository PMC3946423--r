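# polyaRank

Peak-shape-aware re-ranking of transcription-factor ChIP-seq candidate
peaks.

## The problem

Around a true transcription-factor binding site, ChIP-seq reads aligned to
the forward and reverse strands pile up in two separate modes shifted apart
by roughly the fragment length, with the binding site in between. Many
enriched regions with large read counts do not show this pattern — single
strand spikes and other sequencing artifacts — and a caller that ranks by
count alone puts them near the top of its list. `polyaRank` is for analysts
who already have a candidate peak list (e.g. from MACS) and want it
re-ranked so that high-count artifact peaks move down and well-shaped peaks
move up.

## The model

For candidate peak *i*, take an 800 bp window centred on its summit, split
it into 10 bp bins, and count reads per bin separately by strand and by
sample (IP, control; the bin of a read is the bin of its 5'-most base).
This gives a count vector **x**ᵢ with total *T*ᵢ. With *Z*ᵢ ∈ {0,1}
indicating a true binding site and prior P(*Z*ᵢ = 1) = π:

* **Total count.** Under background, *T*ᵢ ~ (1 − ε)·NB(*r*, *p*) +
  ε·U{*a*, *b*}; under binding, *T*ᵢ ~ U{*a*, *b*}. Here (*r*, *p*) are
  fitted by moments to non-peak window counts (after removing runs of ≥ 5
  consecutive zero-count windows), *a* and *b* are the min and max of the
  candidate totals, and ε = 0.001 is fixed. This makes the count likelihood
  ratio increase monotonically in *T* but caps it at 1/ε = 1000, so outlier
  counts cannot dominate.
* **Shape.** Conditional on *T*ᵢ, the bin counts follow a multinomial whose
  probability vector is Dirichlet-distributed — marginally a multivariate
  Pólya (Dirichlet-multinomial) distribution MP(**x** | α). Background and
  binding regions get separate parameter vectors α₀ and α₁, each fitted by
  a Minorization-Maximization (MM) algorithm: α₀ from randomly sampled
  non-peak intervals, α₁ from the top-ranked candidates of the first-step
  caller.
* **Posterior.** Peaks are ranked by
  P(*Z*ᵢ = 1 | **x**ᵢ) = σ(logit π + log LRᵢ), where
  log LRᵢ = [log f₁(*T*ᵢ) − log f₀(*T*ᵢ)] +
  [log MP(**x**ᵢ | α₁) − log MP(**x**ᵢ | α₀)].
  Posteriors that saturate numerically are tie-broken by log LR. The value
  of π shifts all posteriors by the same logit offset and never changes the
  ranking.

A reduced model (`reduced = TRUE`) keeps only the per-sample totals
(IP, control) per peak and runs the identical machinery with length-2
vectors; comparing the two isolates the net contribution of peak shape.

## Worked example

The package ships a seeded simulator so the whole pipeline runs without
external data. Here 100 true sites and 100 shape-artifact sites are drawn
with *matched total-count distributions*, plus 50 background decoy windows:

```r
library(polyaRank)
library(GenomicRanges)

cfg <- simConfig(chromLength = 1e6, nTrueSites = 100, nArtifactSites = 100,
                 nBackgroundCandidates = 50, seed = 42)
sim <- simulateChipSeq(cfg)
res <- scoreChipPeaks(sim$peaks, sim$ip, sim$control, sim$chromLengths,
                      n0 = 1000, seed = 1)

res$models$background
#> BackgroundModel: NB(size = 2.887, prob = 0.3113), uniform on [0, 280], eps = 0.001
head(as.data.frame(res$ranked)[, c("id", "sourceRank", "totalCount",
                                   "logLR", "posterior", "newRank")], 3)
#>          id sourceRank totalCount    logLR posterior newRank
#> 1 site_0099          1        280 69.80873         1       1
#> 2 site_0083         45        145 64.82964         1       2
#> 3 site_0082         28        154 64.49822         1       3

evaluateRanking(mcols(res$ranked)$id, sim$truth, negative = "artifact")$auc
#> [1] 0.9819
```

The fitted background describes the non-peak window counts; each ranked row
reports the peak's total count, its combined count+shape log likelihood
ratio and its posterior. Because artifact totals are matched to true-site
totals, the first-step ranks are interchangeable between the classes
(median source rank 108 for true sites vs 95.5 for artifacts), while the
shape-aware ranking separates them (median new rank 50.5 vs 149.5) — an
AUC of 0.98 for true-vs-artifact discrimination.

File-level equivalents: `runSimulation()` writes BED6 reads, a narrowPeak
candidate list and a truth table; `runPeakRanking()` consumes those files
and writes the ranked TSV plus a JSON report of every fitted parameter.
Command-line wrappers live in `inst/scripts/` (`rank-peaks.R`,
`simulate-chipseq.R`).

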