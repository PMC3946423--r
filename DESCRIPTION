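Package: polyaRank
Title: Peak-Shape-Aware Re-Ranking of ChIP-seq Candidate Peaks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Re-ranks candidate transcription factor ChIP-seq peaks by
    combining total read-count evidence with strand-specific peak-shape
    evidence. Bin-level read counts around each peak summit are modelled
    with multivariate Polya (Dirichlet-multinomial) distributions whose
    parameters are learnt from the data by a Minorization-Maximization
    algorithm; total counts are modelled by a negative-binomial background
    with a uniform outlier component; peaks are ranked by the posterior
    probability of being a true binding site. Includes a seeded simulator
    of strand-shifted bimodal ChIP-seq read data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
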