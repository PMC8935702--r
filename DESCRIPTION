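Package: cftrspectrum
Title: Recessive-Disease Prevalence Estimation and CFTR Genetic-Spectrum
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates the population prevalence of an autosomal recessive
    disease (cystic fibrosis) from exome-cohort carrier counts by three
    estimators, including a beta-binomial Bayesian framework with equal-tailed
    credible intervals; compares carrier-screening panels by restricting the
    detected pathogenic-allele spectrum to a panel; tests cross-population
    allele-frequency differences (odds ratios, chi-square/Fisher, Bonferroni);
    and summarises phased haplotype-block frequency spectra with a joint
    two-SNP genotype association against pathogenic-allele backgrounds.
    Includes a seeded synthetic-cohort generator (Hardy-Weinberg genotype
    draws, gender-stratified carrier tallies, phased haplotype pools with
    optional pathogenic-background enrichment) so every stage is testable
    from printed summary counts alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
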