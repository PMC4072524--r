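Package: selfmix
Title: Divergence, Selfing Syndrome, and Bidirectional Introgression from
    Whole-Genome Haploid Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-genomic analysis of a selfing species and its
    outcrossing progenitor from multi-sample haploid genotype panels:
    site filtering and codon-degeneracy annotation, pairwise and windowed
    nucleotide diversity with block-bootstrap intervals, closed-form split
    time, effective-size and selfing-rate estimators, LD decay profiles,
    a two-state windowed ancestry hidden Markov model with forward-backward
    posterior decoding, admixture-block extraction and tract-length dating,
    a four-population D test with delete-one-chromosome jackknife, a
    single-outlier introgression scan with an exact binomial test, and the
    correlation between local recombination rate and divergence. A
    coalescent and mosaic-genome simulator with known ancestry truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    rlang,
    seqinr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    Biostrings,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
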