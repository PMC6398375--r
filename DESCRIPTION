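Package: orthoselect
Title: Ortholog Calling, Pairwise dN/dS Selection Scans and Expression
    Contrasts for Three-Species Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-transcriptomics pipeline for trios of closely
    related species: three-way reciprocal-best-hit ortholog calling with
    explicit e-value/identity/coverage thresholds, Gaussian-mixture
    filtering of high-dS false positives, Markov-clustering concordance,
    Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction and a
    bounded positive-selection call, rank-based (Mann-Whitney U) Gene
    Ontology enrichment, and a negative-binomial likelihood-ratio
    expression stage with Manhattan-distance principal coordinates and
    marker-based outlier-sample screening. A synthetic-data module
    generates codon alignments, annotations and count matrices with known
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
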