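Package: equidiv
Title: Genomic Diversity and Population Structure Analysis for Horse SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide SNP diversity analysis of
    structured livestock populations, developed around medium-density equine
    genotyping arrays. Reads and writes PLINK text genotypes (PED/MAP), applies
    standard quality control (autosome restriction, SNP call-rate filtering,
    panel intersection), and implements heterozygosity-based and runs-of-
    homozygosity (ROH) based inbreeding coefficients, EM-based linkage
    disequilibrium r2 with distance-binned decay curves and LD pruning,
    sliding-window ROH detection with size-class decomposition and generation
    dating, method-of-moments identity-by-descent, identity-by-state distances
    with classical multidimensional scaling, Weir-Cockerham F_ST, admixture
    modelling by expectation-maximization with cross-validation over the number
    of clusters, and neighbor-joining phylogenies. A synthetic-genotype module
    (Balding-Nichols populations, pedigree gene dropping with recombination,
    Wright-Fisher haplotype pools) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
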