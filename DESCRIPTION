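Package: germdiv
Title: Germplasm Diversity from SNP Genotyping Panels and Transcript Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for diversity surveys of clonally maintained
    germplasm collections genotyped on biallelic SNP panels. Provides
    missingness-based genotype quality control, per-locus diversity
    statistics (polymorphism information content, minor allele frequency,
    observed and expected heterozygosity, the fixation indices F_S and
    F_ST), proportion-of-shared-alleles distances with Ward dendrograms and
    locus-bootstrap branch support, a maximum-likelihood admixture model
    fitted by EM with Evanno delta-K selection of the number of ancestral
    populations, and transcript-level variation classifiers (joint SNP
    genotype categories, longest-ORF assignment, perfect microsatellite
    scanning). A Balding-Nichols synthetic-data generator with known ground
    truth drives testing of every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    ape,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
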