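Package: regbuildr
Title: Consensus Regulatory Annotation from Multi-Cell-Type Genome Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates per-cell-type genome segmentations, transcription factor
    ChIP-seq peak calls and open-chromatin peaks into a single consensus
    annotation of regulatory features (promoters, proximal and distal enhancers,
    CTCF binding sites, unannotated TF binding sites and open chromatin), each
    annotated with per-cell-type binary activity. Segmentation states are
    assigned functional labels from fold enrichments against TF binding, TSS and
    exon annotation plus correlation to CTCF binding density; per-label
    cross-cell-type summary functions are thresholded at the integer cutoff that
    maximizes an F-score against the combined TF binding probability track.
    Includes genome-wide step-function algebra on run-length encoded coverage
    vectors, readers and writers for BED, bedGraph and GFF3, and a deterministic
    synthetic-epigenome generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
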