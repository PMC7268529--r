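Package: ploidtrace
Title: Selection Footprints and Whole-Genome-Duplication Dating from
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for molecular-evolution screens on
    multi-species transcriptome assemblies: identification of protein-coding
    regions (annotation-guided or six-frame ORF), cross-species protein
    homology graphs clustered into gene families by Markov clustering,
    single-copy-ortholog phylogenies (neighbor joining with bootstrap),
    Nei-Gojobori (NG86) Ka/Ks selection screening with Fisher validation and
    threshold-based selection classes, hypergeometric functional-term
    enrichment with Bonferroni correction, and whole-genome-duplication
    dating from paralog Ks age distributions via Gaussian-mixture peak
    fitting and T = Ks/2r.  Includes a synthetic-data generator that plants
    ortholog pairs at target Ka/Ks, paralog pairs with mixture-distributed
    Ks, and enriched annotation terms, so every stage is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
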