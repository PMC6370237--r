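Package: lethalmap
Title: Discovery and Characterisation of Recessive Lethal Alleles Under
    Balancing Selection in Pedigreed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the inference chain used to discover and characterise
    a recessive lethal mutation maintained by heterozygote advantage in a
    closed livestock breeding population: within-litter segregation-ratio
    tests and Bayesian monogenic segregation analysis by Gibbs sampling,
    case/control homozygosity mapping of shared autozygous segments,
    recessive candidate-variant filtering from multi-sample VCF with
    GATK-style site hard filters and premature-stop consequence annotation,
    Hardy-Weinberg distortion analysis across life stages (alpha statistic),
    variance components and heritability for a binary trait with the
    Dempster-Lerner liability transformation, and pedigree mixed-model
    genotype-trait association. A forward population simulator generates
    synthetic pedigrees, SNP-chip genotypes, phenotypes and variant calls
    with the statistical structure the analyses assume, so the whole chain
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
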