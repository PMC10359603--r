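Package: dufscout
Title: Discovery and Characterization of DUF6499-DUF2285 Activator
    Systems from Genomic Sequence
Version: 0.1.0
Authors@R:
    person("dufscout", "maintainers", email = "dufscout@example.org",
           role = c("aut", "cre"))
Description: Tools to discover and characterize DUF6499+DUF2285
    transcriptional activators (FseA-like) and their lone-DUF2285
    antiactivator paralogues (QseM-like) on mobile genetic elements.
    Reconstructs full-length activator polypeptides across +1 programmed
    ribosomal frameshift (PRF) sites that join overlapping open reading
    frames, curates candidate homologues with motif-based filters, scans
    promoter regions for inverted-repeat operator boxes with split-anchor
    conservation profiling, computes formal domain charge, fits
    specific-binding-with-Hill-slope models to electrophoretic mobility
    shift assay (EMSA) quantitations, and computes superposition-based
    RMSD statistics over multi-model structure ensembles. A synthetic-data
    generator with recorded ground truth makes every stage testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
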