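Package: chadolite
Title: Embedded Chado-Compatible Genomics Data Store with Loaders,
    Queries and Faceted Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An embedded, file-backed genomics data store whose tables
    mirror the subset of the GMOD Chado 1.31 relational schema used by
    genome annotation portals.  Provides loaders for OBO ontologies,
    genome and protein FASTA, GFF3 feature hierarchies, BLAST tabular
    results, InterProScan TSV, OrthoMCL-style ortholog groups, MCL
    coexpression clusters, BibTeX publications and expression matrices
    with assay metadata; a query layer assembling feature-page details,
    genome-browser region queries and sequence/table export; an
    in-process search index with keyword autocomplete and faceted
    filtering; a deterministic synthetic fixture-bundle generator; and a
    command-line interface over all of it.  Coordinates are stored in
    Chado's interbase (0-based, half-open) convention and converted
    from/to 1-based formats at the boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
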