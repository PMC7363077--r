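Package: mtduplex
Title: Duplex-Sequencing Analysis of Mitochondrial DNA Mutations and Heteroplasmy Drift
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting low-frequency de novo mitochondrial DNA mutations
    and quantifying drift of inherited heteroplasmies from barcoded duplex
    sequencing data. Implements tag-family grouping with barcode error
    correction, single-strand and duplex consensus calling, circular-genome
    pileup and variant calling at DCS and SSCS level, classification of variants
    into tissue-specific de novo mutations, early somatic mutations and
    inherited heteroplasmies, mutation-frequency statistics (region, strand,
    CpG, trinucleotide spectra, permutation and exact tests, Poisson intervals,
    false discovery rate control), a Nei-Gojobori hN/hS selection test with a
    bootstrap neutral null, an effective germline bottleneck estimator with
    bootstrap confidence intervals, and binomial mixed-effects modelling of
    mutation frequency with marginal, conditional and partial pseudo-R-squared.
    A seeded synthetic-data generator emulates two-generation mouse pedigrees,
    binomial bottleneck transmission of heteroplasmies, age- and tissue-
    dependent mutation rates, and barcoded duplex read families, so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    yaml
Config/testthat/edition: 3
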