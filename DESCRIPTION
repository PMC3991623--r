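Package: gbstk
Title: Genome Sampling and Genotype Filtering Assessment for Genotyping-by-Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess genotyping-by-sequencing (GBS) experiments built on
    methylation-sensitive restriction digests. Provides reference-free tag-pair
    SNP calling (64-bp tag collapse, distance-1 pairing with network resolution,
    depth cap and minor-allele-frequency pre-filters), three read-depth-aware
    genotype filtering strategies (threshold, ambiguity and within-genotype
    minor-allele-fraction filters) with missingness pruning, technical-replicate
    concordance and depth-association tests, population-genetic summaries
    (Hardy-Weinberg exact test, observed and expected heterozygosity, overall
    and pairwise gene-diversity F_ST with region contrasts), an in silico
    restriction-digest module quantifying gene-region sampling bias and
    multiplexing trade-offs, and a synthetic-data generator emulating
    hierarchical population structure, overdispersed read depths, allelic
    dropout and technical replication for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, Sequencing, PopulationGenetics, QualityControl
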