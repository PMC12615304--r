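Package: protegap
Title: Proteogenomic Reassessment of Gene Models by Six-Frame Open Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale proteogenomics pipeline for ciliate-style genomes:
    builds combined six-frame/three-frame search databases under the ciliate
    nuclear genetic code, identifies peptides by a simplified open
    modification search with target-decoy false discovery rate control,
    classifies genome search-specific peptides (GSSPs), calls novel
    protein-coding genes from clustered GSSPs, audits annotated gene models
    for start/stop/intron errors, assigns precursor mass deltas to a
    modification catalog, and integrates NSAF protein abundance with FPKM
    transcript abundance across life-cycle states. Ships a synthetic-data
    generator with a complete ground-truth ledger so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
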