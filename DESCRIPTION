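Package: relic
Title: Evolutionary Constraint Classification of Regulatory Elements via
    Alignment Chains
Version: 1.0.0
Authors@R:
    person("Ming", "Developer", email = "relic-maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the evolutionary constraint of cis-regulatory
    elements (REs) by projecting them across genomes through UCSC alignment
    chains. Computes per-element aligned-base fractions against a panel of
    target genomes (a conservation matrix), classifies elements into
    hierarchical constraint tiers (cross-species constrained, clade-specific,
    reference-species-specific), annotates genomic context and nearest genes,
    aggregates per-base conservation scores, measures transposable-element,
    motif and QTL overlap per tier, and summarises trends by divergence-time
    regression and principal component analysis. Includes a coordinate-level
    genome-evolution simulator that emits truth-labelled regulatory elements
    and valid chain files whose alignment loss grows with branch length, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
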