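Package: cdr3profiler
Title: Profiling of TCR-Beta CDR3 Immune Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterization of T-cell receptor beta-chain CDR3 repertoires
    from rearrangement tables (immunoSEQ-style or AIRR Rearrangement TSV):
    junction translation and productivity classification, CDR3 length
    distributions and moment summaries, theoretical isoelectric points,
    residue physicochemical composition, Simpson clonality, class I pMHC
    immunogenicity scoring by an amino-acid enrichment model, cross-sample
    clonotype sharing with Clustal-style conservation annotation, and
    nonparametric group comparison via Dunn's rank test. Includes a seeded
    synthetic repertoire generator that provides ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, ImmunoOncology, TargetedResequencing, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
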