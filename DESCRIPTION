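Package: dmrlink
Title: Methylome-Transcriptome Integration for Contrasting Stress-Response Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and integration of whole-genome bisulfite
    sequencing and RNA-seq results for experimental designs that contrast
    two phenotype groups (for example drought-tolerant versus
    drought-sensitive genotypes) under control and stress treatments.
    Provides readers for per-cytosine methylation reports, gene
    annotation and count matrices; window-based differential methylation
    calling with context-specific effect-size thresholds; merging of
    per-genotype DMRs into group-conserved regions with genotype-support
    filtering; a documented stand-in differential-expression test and DEG
    set algebra; hypergeometric pathway enrichment with four-way set
    intersection; a methylation-expression negative-regulation screen
    with a weighted priority score for ranking candidate genes; metagene
    methylation profiles by expression group; and a synthetic-data
    generator with planted effects so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
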