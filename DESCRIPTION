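Package: ovisnp
Title: Candidate-Gene SNP Association, Haplotype and Expression Analysis for Sheep Reproductive Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy toolkit for candidate-gene single-nucleotide-polymorphism studies of
    reproductive traits in livestock, built around a litter-size study of SMAD1, SMAD2 and
    SMAD3 in Tibetan sheep. Computes per-locus population-genetic indices (allele and
    genotype frequencies, expected homozygosity and heterozygosity, effective allele
    number, polymorphism information content) with chi-square and exact Hardy-Weinberg
    tests; estimates multi-locus haplotype frequencies from unphased genotypes by
    expectation-maximisation with D'/r-squared linkage disequilibrium and block reports;
    fits a fixed-effects litter-size model with parity-by-genotype interaction, Type III
    F tests and compact letter displays; performs 2^-ddCt relative-expression analysis
    with tissue-level comparisons; and provides sequence utilities (open reading frames,
    translation, protein physicochemical parameters, neighbor-joining trees). A seeded
    synthetic-data module generates genotype, phenotype, Ct and coding-sequence fixtures
    with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    withr,
    car,
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    vcfR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
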