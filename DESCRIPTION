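Package: epiprime
Title: Multi-Omics Reconstruction of De Novo Methylation-Dependent Gene
    Regulation During Exit from Pluripotency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for identifying de novo
    methylated regions that depend on a DNA methyltransferase (DNMT3B-style
    knockout designs), calling their downstream target genes by integrating
    whole-genome bisulfite, expression and active-chromatin data, and
    reconstructing the methylation-dependent transcription-factor network
    with direct/indirect evidence classification, out-degree prioritisation
    and Fisher-exact activity scoring. Includes differential methylation
    testing with run-based segmentation, trajectory clustering of region
    dynamics, rank-elbow super-enhancer calling, randomisation-based
    annotation enrichment, region-to-gene association rules, and a
    synthetic-data generator with planted ground truth that emulates a
    WT/knockout embryonic stem cell to meso-endoderm differentiation time
    course, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
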