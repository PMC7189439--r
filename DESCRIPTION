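Package: conclaveR
Title: ConClave-Based Taxonomic Classification of Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained metagenomic classification pipeline built
    around the ConClave sorting scheme: reads are scored against every
    candidate reference template with a k-mer index, templates are ranked
    by their accumulated score over all reads, and each read is then
    assigned to its highest-ranked candidate, resolving reads shared
    among near-identical references. Surviving template matches are
    quality-filtered and classified at the lowest taxonomic rank their
    sequence identity supports, using an NCBI-taxdump-style taxonomy.
    Includes Krona and OTU-style table export, per-rank precision,
    recall and F1 benchmarking against truth sets, and a synthetic
    microbial community simulator (references, taxonomies, reads and
    truth tables) so the whole pipeline can be validated without
    external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
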