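Package: lohma
Title: Loss of Heterozygosity, Copy Number and Mutation Rate Analysis for
    Yeast Mutation Accumulation Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse mutation accumulation (MA) experiments in
    heterozygous diploid yeasts. Calls loss-of-heterozygosity (LOH) tracts
    from per-line genotypes at parental heterozygous SNP positions, measures
    tract lengths by the flanking-heterozygous-SNP midpoint convention,
    classifies tracts as terminal or interstitial and maps cross-line LOH
    hotspots at base-pair resolution. Detects whole-chromosome aneuploidy and
    segmental copy-number changes from binned read depth, detects de novo
    single-nucleotide mutations against the parent genotype and estimates
    per-base per-generation mutation rates with between-background
    comparisons. Includes a synthetic MA-line simulator that emits genotype
    matrices, per-line VCFs, binned coverage and a planted-event truth table
    so every caller can be validated end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
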