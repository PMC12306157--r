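Package: PEscan
Title: Detection and Classification of Palindromic Elements in Prokaryotic Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seed-and-extend discovery of palindromic elements in the
    intergenic regions of annotated bacterial and archaeal genomes.
    Candidate stem-loops are seeded from exact reverse-complementary k-mer
    pairs, extended while Watson-Crick or G-T wobble pairing holds,
    assembled across short bulges, scored with an additive hairpin energy
    model, and classified as Rho-independent terminators (RITs) or
    repetitive extragenic palindromic elements (REPs) by a thymine-tail
    score. Includes intergenic-region extraction from GFF3 annotation,
    TSV/BED/FASTA writers, per-window strand density summaries, a motif
    group similarity score, and a synthetic-genome generator with ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SequenceMatching, Annotation, GenomeAnnotation
RoxygenNote: 7.3.3
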