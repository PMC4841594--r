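Package: ecrfoot
Title: Phylogenetic and Epigenetic Footprinting of Conserved Regulatory Elements
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising evolutionarily conserved regions (ECRs)
    as candidate cis-regulatory elements, modelled on the analysis of the
    imprinted Peg3 domain. Calls conserved elements between two genomic
    intervals (length > 50 bp, identity > 75%), finds their orthologs across
    species with a seed-and-extend search, anchors ortholog sets into
    reference-based multiple alignments, detects invariant sub-regions
    (phylogenetic footprints), scans IUPAC motifs on both strands and scores
    per-element motif enrichment, performs in-silico COBRA (bisulfite
    conversion, amplicon extraction, restriction enzyme informativeness,
    digestion prediction, densitometric methylation quantification, and
    replicate-supported hypo/hypermethylation calls), and classifies per-tissue
    enhancer chromatin states (H3K4me1/H3K27ac) with breadth calls. A
    synthetic-data module generates every input with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
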