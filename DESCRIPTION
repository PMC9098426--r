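Package: circasplice
Title: Circadian Rhythmicity and Alternative Splicing Analysis of
    Time-Course Transcript Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ~24 h rhythmic transcripts and genes in time-course
    expression matrices using cosinor harmonic regression and a
    nonparametric umbrella rank permutation test, enumerates the seven
    local alternative-splicing event modes (A3, A5, AF, AL, MX, RI, SE)
    from transcript annotation, computes percent-spliced-in (PSI)
    profiles from transcript abundances, classifies gain and loss of
    splicing events between a knockout and its control, and tests
    within-gene transcript-isoform pairs for differential rhythmicity
    and phase shifts. Ships a synthetic time-course generator with known
    ground truth, gene-set reporting (splicing factors, cancer
    hallmarks), and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
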