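Package: peaklink
Title: Summit-Window Integration of Chromatin Accessibility with Cistrome
    and Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing ATAC-seq peak landscapes between treatment
    conditions and integrating them with transcription-factor cistromes and
    differential-expression results. Implements summit-centered window overlap
    classification of shared versus condition-specific accessible regions,
    prioritized genomic-feature annotation (promoter, UTRs, exon, intron,
    intergenic) with nearest-TSS peak-to-gene assignment, differential
    accessibility testing over merged peak universes from Tn5 cut-site counts,
    aggregate signal metaprofiles around peak centers and transcription start
    sites, comparative-Ct (2^-ddCt) quantification, and a fully seeded
    synthetic-data generator with recorded ground truth so every stage of the
    workflow can be validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
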