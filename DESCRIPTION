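Package: nucsort
Title: Simulation and Analysis of Marker-Sorted Nuclei RNA-seq Experiments
Version: 0.1.0
Authors@R:
    person("Patrick", "Reilly", email = "preilly@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of transcription-factor-based
    nuclei sorting experiments in brain tissue: simulation of flow-cytometry
    event tables, spliced/intronic/genomic-DNA read mixtures and qPCR plates
    with known ground truth; axis-aligned gating and in-silico sorting;
    removal of genomic-DNA background by retaining only splice-junction
    spanning alignments; junction-read gene quantification (counts, TPM,
    RPM); cell-type marker-panel log2 enrichment statistics with marker
    refinement and sample QC; and housekeeping-normalised qPCR fold
    enrichment. A single-command pipeline reproduces the full desk-scale
    experiment from one seeded configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
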