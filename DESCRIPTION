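Package: peptax
Title: Taxonomy-Aware Metaproteomics Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for taxonomy-aware analysis of shotgun metaproteomics data:
    in-silico proteolytic digestion and nonredundant peptide indexing of
    multi-organism protein databases, cross-database shared-peptide overlap
    analysis, lowest-common-ancestor placement of observed peptides on a
    ranked taxonomy, protein grouping constrained to a single taxon at a
    chosen split rank (so that peptides shared between, say, phyla never
    drive identification), and top-N peptide-intensity quantification of
    bacterial genera from MaxQuant-style evidence tables. Includes a
    synthetic-data generator that emulates multi-species databases with
    tunable within-genus sequence identity and multi-sample log-normal
    intensity evidence with planted genus abundances, so every analysis step
    can be exercised and validated without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
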