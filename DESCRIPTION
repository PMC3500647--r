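Package: bovrep
Title: Simulation and Analysis of Bovine IgG Heavy-Chain Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing expressed immunoglobulin G heavy-chain
    (VH) repertoires from high-accuracy circular consensus amplicon reads:
    per-base Phred quality filtering, framework-1 anchored reading-frame and
    strand determination, rule-based extraction of the complementarity
    determining regions (CDR1-3), repertoire descriptive statistics
    (per-position Shannon entropy, amino-acid composition, CDR3 length
    distributions and bimodality, cysteine count and position regressions),
    and paratope similarity networks built from all-vs-all local alignment
    with Karlin-Altschul E-value thresholds and clustering-coefficient
    summaries. Includes a bovine-constrained V(D)J recombination, somatic
    hypermutation and CCS read simulator with full ground truth, so every
    stage of the pipeline can be validated against known rearrangements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
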