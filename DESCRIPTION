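Package: esalign
Title: Embed-Search-Align: Short-Read Alignment via Contrastive DNA Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns short DNA reads to a reference genome by vector search
    instead of seed-and-extend indexing. A reference-free DNA embedding (RDE)
    transformer encoder is trained by contrastive self-supervision so that a
    read and the reference fragment it originates from map to nearby points
    under cosine distance. The reference is sharded into overlapping
    fragments, embedded, and stored in a local vector index; each read is
    embedded, the top-K nearest fragments per chromosome are retrieved, and a
    Smith-Waterman fine-alignment (minimization convention, affine gaps)
    recovers the global position. Includes a synthetic-genome generator with
    planted repeats, an ART-like read simulator with Phred-governed
    substitution and indel noise, recall evaluation with exact
    Clopper-Pearson confidence intervals, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
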