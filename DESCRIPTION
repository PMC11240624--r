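Package: pavpipe
Title: Gene Presence-Absence Variation Calling, Pangenome
    Classification, and PAV-Based Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coverage-based detection of gene presence-absence variation
    (PAV) from whole-genome sequencing depth, with downstream pangenome
    frequency classification (core, softcore, shell, cloud), PAV-based
    population genetics (principal components, neighbor-joining trees),
    and single-marker association of binary gene PAVs with de-regressed
    predicted transmitting abilities under Bonferroni significance tiers.
    Includes a fully seeded synthetic-data generator (annotation, per-base
    depth, phenotypes with planted effects) so every stage of the pipeline
    is testable without restricted cattle data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    GenomicAlignments,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
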