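Package: endobin
Title: Deconvolution of Host-Endosymbiont Assemblies by Composition,
    Read-Pair Graphs and Ensemble Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates the contigs of a target endosymbiont from a mixed
    host-symbiont assembly. Combines partial taxonomic affiliations from
    homology searches (via a TaxonDensity consensus filter), canonical
    k-mer composition and fragment coverage, a read-pair linkage graph
    used to extend and correct labels, repeated random-forest and
    support-vector-machine ensemble classification with per-contig vote
    fractions, and a final UMAP + DBSCAN clustering step anchored on the
    target 16S rRNA contig. Includes a truth-annotated synthetic mixture
    generator and count- and length-weighted binning performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    igraph,
    randomForest,
    e1071,
    uwot,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
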