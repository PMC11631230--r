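Package: strainsweep
Title: Strain-Resolved Dynamics of Viral Communities from Metagenomic Read
    Recruitment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects selection of rare viral genotypes in time-course
    metagenomes by fragment recruitment. Provides a synthetic viral community
    generator (a two-species genus with intra-species variant groups, a
    hypervariable genomic island and a sweeping rare genotype), an ungapped
    seed-and-extend read aligner with identity and coverage filters,
    normalized genotype abundance and fold change, metagenomic-island
    detection and time-course status, VIRIDIC-style intergenomic similarity
    with ICTV species/genus thresholds, reciprocal-best-match amino-acid
    identity and group clustering, amplicon phylotype profiling with
    rarefaction and Shannon diversity, codon-level synonymous and
    nonsynonymous variant counting, and MinHash (Mash) metagenome distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    igraph,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
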