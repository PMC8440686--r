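Package: RDReanalysis
Title: Programmatic Reanalysis and Variant Re-Prioritization for Undiagnosed Rare-Disease Cases
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A scriptable variant re-prioritization engine for periodic
    reanalysis of undiagnosed rare-disease exome/genome cases. Implements a
    configurable filter stack over annotated variant calls joined with
    standardized phenotype (HPO/ORDO/OMIM) and pedigree data: rarity filters
    against external and internal cohort allele frequencies, curated or
    phenotype-driven on-the-fly gene panels, ClinVar-style pathogenicity
    assertions, inheritance-aware segregation analysis, runs-of-homozygosity
    detection with consanguinity inference, compound-heterozygote pairing, a
    CNV cross-check for suspect homozygous calls, candidate-table reporting,
    case-status tracking across reanalysis rounds, and cohort summary
    statistics. Ships a seedable synthetic-cohort generator so the entire
    workflow is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
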