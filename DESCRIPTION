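Package: wreconserve
Title: Cross-Species Conservation Analysis of TCF/LEF (WRE) Promoter Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Degenerate Wnt response element (WRE, TCF/LEF) motif scanning of
    TSS-anchored promoter windows on both strands, cross-species conserved-site
    calling from gapped promoter alignments, nucleotide distance estimation
    (p-distance, Jukes-Cantor, Tamura-Nei 1993, and a shared-parameter
    composite-likelihood TN93 mode) with Neighbor-Joining tree construction,
    design and validation of wild-type versus site-mutant luciferase reporter
    inserts, and a promoter-evolution simulator with known ground truth for
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coords.R'
    'promoter-io.R'
    'motif.R'
    'scan.R'
    'conservation.R'
    'distances.R'
    'nj.R'
    'simulate.R'
    'reporter.R'
    'pipeline.R'
    'wreconserve-package.R'
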