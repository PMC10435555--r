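Package: ervi
Title: Discovery and Population Genotyping of Invading Endogenous Retroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies proviral elements bounded by identical long terminal
    repeats (LTRs) and target-site duplications in genome assemblies, filters
    them for retroviral origin and replication intactness (gag-pro-pol-env
    structure, RT-RH-IN domain order, transmembrane motif, no premature stop
    codons), genotypes insertional polymorphism in population sequencing reads
    via junction queries, clusters elements into viral operational taxonomic
    units with Markov clustering, and provides the downstream statistics used
    in invading-ERV surveys: BCa bootstrap richness extrapolation, the
    phylogenetic-signal D statistic for binary traits, and the G-test of
    independence. Includes a synthetic-data generator that builds reference
    panels, genomes with implanted proviruses, diploid populations and
    sequencing reads with machine-readable truth, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
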