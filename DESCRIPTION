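Package: popkit
Title: Post-Variant-Calling Population Genomics for Resequenced Diploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis stages that follow multi-sample variant
    calling in conservation and population genomics: a composable SNP
    filtering cascade (GATK-style hard filters, aggregate depth bounds,
    mappability mask exclusion, minor allele frequency, call rate, scaffold
    length, LD pruning), windowed nucleotide diversity with equal-sample-size
    resampling, per-individual heterozygosity and polymorphism proportions,
    windowed Weir-Cockerham FST with a subsampling null for within-population
    substructure, PCA and a K-cluster admixture model fitted by EM with
    cross-validation, PLINK-semantics runs-of-homozygosity detection with
    coverage-normalised F_ROH, and minimum spanning networks for aligned
    mitochondrial haplotypes. Includes a Balding-Nichols genotype simulator
    with ground truth for validating every stage without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
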