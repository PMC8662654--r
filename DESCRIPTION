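Package: evoreseq
Title: Evolve-and-Resequence Time-Series Analysis for Experimentally
    Evolved Microbial Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal whole-population sequencing of
    experimentally evolved microbial populations propagated by daily serial
    transfer (planktonic) or a bead model of the biofilm life cycle. Reads and
    filters polymorphism calls (strand support, dense-window exclusion,
    ancestral subtraction, repeat masking), consolidates them into
    per-population frequency trajectory tables, clusters mutations into
    genotypes by shared nested trajectories, infers Muller genealogies and
    fixation events, scores gene-level parallelism with locus-length-aware
    Fisher exact tests and Benjamini-Hochberg correction, normalises dN/dS
    against a codon-usage neutral expectation, computes alpha-diversity
    trajectories and environment-enrichment classification via Cook's
    distance, and estimates fitness (selective rate constant), maximum growth
    rate, and mutation rates by Luria-Delbruck fluctuation analysis. A
    forward-time Wright-Fisher serial-transfer simulator with clonal
    interference, mutator lineages, and sequencing-noise emulation provides
    ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    vegan,
    vcfR,
    Biostrings
Config/testthat/edition: 3
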