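Package: ripcpe
Title: RIP-Seq Binder Calling and CPE Motif Analysis of 3'-UTRs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for characterizing the target spectrum of
    an RNA-binding protein from RIP-Seq data. Calls "binder" transcripts from
    IP-versus-control count enrichment using a negative-binomial Wald test with
    median-of-ratios normalization and Benjamini-Hochberg multiple-testing
    adjustment, scans transcript 3'-UTRs for the four cytoplasmic
    polyadenylation element (CPE) classes (consensus CPE, non-consensus CPE,
    the polyadenylation hexanucleotide, and the Pumilio-binding element), and
    compares binders against non-binders by element counts, per-kilobase
    densities, and UTR length (Fisher exact and rank-sum tests), with an
    optional logistic binder-probability score. A seeded synthetic-data module
    generates UTR sequences and RIP-Seq count matrices with known ground truth
    so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
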