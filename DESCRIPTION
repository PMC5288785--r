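Package: markexpr
Title: Integration of Histone-Mark ChIP-Seq Enrichment with Expression
    Fold Changes in Two-Genotype Designs
Version: 0.1.0
Authors@R:
    person("Sertoli", "Epigenomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-level analysis of bulk mRNA-seq and histone-mark ChIP-seq
    across two genotypes. Computes FPKM expression values, inter-genotype
    fold changes and threshold-based differential-expression classes;
    scores per-gene H3K4me3 and H3K27me3 enrichment as the RPM-normalized
    ChIP/input ratio over mark-specific windows (TSS-centered for H3K4me3,
    upstream-flank-to-TTS for H3K27me3); compares mark levels between
    genotypes within expression classes with Welch t-tests; builds
    TSS-centered and scaled-gene-body metagene read-density profiles; and
    produces joint expression/mark fold-change reports. Includes a full
    synthetic-study generator (gene models, negative-binomial count tables
    and ChIP/input read libraries with planted mark-expression coupling)
    so the entire pipeline is testable without sequencing data, plus a
    command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
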