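Package: igclone
Title: V(D)J Recombination Signatures and Their Genotyping Impact in
    LCL-Derived Short-Read Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects somatic V(D)J recombination in short-read whole-genome
    sequencing of the immunoglobulin heavy-chain (IGH) locus from
    lymphoblastoid cell lines. Infers B-cell clone composition from
    discordant read pairs joining IGHJ and IGHV gene segments, estimates the
    size of the excised interval for the dominant clone, and quantifies the
    downstream distortion of heterozygous genotype calls, allele-frequency
    estimates, and haplotype linkage disequilibrium. Ships a seeded
    simulator of clonal B-cell pools (germline phased SNPs, per-clone
    deletions, somatic hypermutation, paired-end alignment records) so the
    whole analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
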