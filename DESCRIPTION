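Package: chromsort
Title: Analysis of Flow-Sorted Single-Chromosome Long-Read Sequencing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis for chromosome flow-sorting enrichment
    experiments sequenced with long reads: per-chromosome coverage and
    enrichment/depletion folds against a diploid-male sampling null,
    assembly contiguity and mutual-coverage evaluation, harmonization of
    assembly-based and read-based structural-variant callsets (filtering,
    reciprocal-overlap intersection, novelty classification, size spectra),
    superpopulation allele-frequency summaries from population genotype
    tables, and Kimura 2-parameter repeat divergence landscapes. Includes a
    synthetic-data generator with known ground truth so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
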