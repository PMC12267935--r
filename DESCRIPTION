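Package: longco
Title: Direct Mapping of Meiotic Crossovers in Pooled Long-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meiotic crossovers directly in long sequencing reads from
    pooled recombinant DNA (e.g. hybrid pollen or pooled F2 seedlings). Each
    aligned read is converted into a parental-genotype string over a curated
    biallelic SNP catalog and classified as parental, simple crossover (SCO) or
    complex crossover (CCO) under a parameterized rule family. Includes SNP
    catalog curation from F2 genotype matrices, base-quality masking, depth and
    negative-control blacklists, validation against orthogonal truth sets
    (precision, false negatives), per-genome crossover-rate normalization by
    read subsampling, a log-linear saturation model for pool-size design,
    genome- and gene-scale crossover landscape statistics, and a synthetic
    pollen-pool simulator with a per-read truth ledger so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
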