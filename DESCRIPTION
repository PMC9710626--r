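Package: modhub
Title: Disease Module Inference and Hub Regulator Filtering on Molecular
    Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers transcriptomic disease modules on a protein-protein
    interaction network by Clique-Sum scoring of maximal cliques, predicts
    hub transcription-factor regulators by averaging regulator outdegree
    across a compendium of gene regulatory network inference methods,
    reduces modules to the genes regulated by statistically enriched hubs
    (Fisher's exact test), evaluates modules by hypergeometric
    over-representation analysis against GMT collections, and validates
    candidate regulators by permutation-based SNP enrichment in binding
    regions together with eQTL fold-enrichment. Ships a synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cliques.R'
    'enrichment.R'
    'grn.R'
    'hubfilter.R'
    'io.R'
    'modhub-package.R'
    'pipeline.R'
    'regions.R'
    'simulate.R'
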