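Package: gesskit
Title: Service-Sire and Dam Genetic Effects on Female Reproductive Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of the genetic effect of the
    service sire (GESS) and of the dam (GED) on female reproductive traits
    in dairy cattle (conception rate, 56-day non-return rate, calving ease,
    stillbirth, gestation length). Provides pedigree relationship algebra
    (inbreeding, numerator relationship matrix and its sparse inverse), a
    correlated two-genetic-effect linear mixed model with AI-REML variance
    component estimation and delta-method standard errors, BLUP breeding
    values with reliabilities and de-regressed proofs, a FarmCPU-style
    multi-locus genome-wide association scan with genotype quality control,
    false-discovery-rate control and inflation diagnostics, window-based
    positional annotation of significant markers, and a synthetic herd
    generator that emulates the data structure the model assumes (skewed
    service-sire usage, repeated parities, herd-year-month contemporary
    groups, correlated sire and dam breeding values).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
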