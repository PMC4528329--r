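Package: annotriage
Title: Evidence-Based Triage and Curation of Gene Model Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, configurable re-implementation of the curation
    computations used to maintain a manually annotated gene model set against
    high-throughput transcriptome evidence: transcription start site
    refinement by the 90% signal point, RNA-Seq splice-junction triage under
    relative-frequency and frame rules, gene merge and split proposals,
    sliding-window RPKM scans for intergenic transcription and lncRNA
    discovery, 3' UTR extension and polyadenylation-site clustering, ORF
    finding with subgroup-style conservation assessment, pseudogene and
    mutation-in-strain classification from coding lesions, splice-graph
    isoform accounting with representative transcript selection, and
    sex-biased expression classification. Includes a seeded synthetic-data
    generator that emulates the evidence tracks (coverage, junctions, TSS
    signal, cDNA alignments, ortholog sets) with ground-truth tables for
    every classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
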