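Package: lesionevo
Title: Clonal Evolution Analysis of Matched Precursor and Carcinoma Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream genomic analysis for matched multi-region lesion
    cohorts (normal myometrium, normal gland, precursor, carcinoma):
    germline subtraction and quality filtering of somatic variant tables,
    copy-number and copy-neutral-LOH calling with a normal-derived minor
    allele fraction cutoff, haplotype-aware event interpretation,
    96-context mutational signature refitting by non-negative least
    squares, exhaustive-search Fitch parsimony phylogenies with lesion
    topology classification, and a cancer-gene-census style candidate
    driver scoring system. A bundled clonal-evolution simulator with a
    truth ledger makes every stage testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
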