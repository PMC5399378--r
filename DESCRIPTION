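Package: mirforge
Title: Genome-Wide microRNA Discovery from Homology, Hairpin Structure,
    and Small RNA Evidence
Version: 0.1.0
Authors@R:
    person("mirforge", "developers", email = "mirforge@example.org",
           role = c("aut", "cre"))
Description: A three-track pipeline for cataloguing candidate microRNA
    (miRNA) genes in a draft genome: mismatch-limited homology search
    against known mature miRNAs, structure-only de novo hairpin scanning
    with a length sweep, and discovery guided by small RNA sequencing
    reads mapped across species.  All tracks share one filtration engine
    (length, single hairpin loop, GC content, paired-base fraction, and a
    length-dependent minimum-free-energy threshold), mature 5p/3p arm
    inference from paired-segment patterns, strand inference from layered
    evidence, cross-track merging with Venn accounting, seed-based family
    assignment, conservation classification, a precursor-compendium
    criteria benchmark, and seed/duplex-energy scanning of 3' UTRs for
    candidate targets.  A deterministic synthetic-data generator plants
    canonical precursors, reads, and reference matures with ground truth
    so every stage is testable without downloads.  Secondary-structure
    folding uses a built-in simplified nearest-neighbor thermodynamic
    model (Zuker-style dynamic programming) behind a narrow contract.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
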