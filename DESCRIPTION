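Package: swstripe
Title: Striped and Partitioned Smith-Waterman Protein Database Search
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact Smith-Waterman local alignment with affine gap penalties
    for protein database search, built around three provably score-equivalent
    engines: a scalar dynamic-programming reference, a striped vectorized
    engine with a lazy-F correction loop running on an emulated virtual SIMD
    lane machine, and a partitioned vectorized engine that splits the query
    into fixed-length partitions and carries per-column boundary scores
    between partitions. Includes BLOSUM substitution matrices, sequential
    and striped query profiles, FASTA database search with ranked results
    and GCUPS throughput reporting, and seeded synthetic protein sequence
    generators for reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Alignment, SequenceMatching, Proteomics, Software
RoxygenNote: 7.3.3
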