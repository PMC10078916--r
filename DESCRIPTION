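Package: hybridclass
Title: Bayesian Classification of Hybrids from Linked SNP Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Full-likelihood Bayesian classification of diploid individuals
    into six two-generation genealogical classes (pure parental, F1, F2 and
    the two backcrosses) from phased or unphased biallelic SNP data on
    linked markers. Recombination along each chromosome is modelled as a
    no-interference Poisson crossover process, so the likelihood of a
    recombinant haplotype is an exact sum over per-marker population
    ancestry states weighted by segment haplotype frequencies. Includes
    Dirichlet-multinomial estimation of population haplotype frequencies
    from reference panels, an unlinked composite-likelihood baseline
    classifier with known allele frequencies, a factorial simulator of
    haplotype panels and per-class diplotypes, and calibration, power and
    ROC performance metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
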