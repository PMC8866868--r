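Package: snpsnpmix
Title: SNP-SNP Microhaplotype Analysis of Unbalanced Degraded DNA
    Mixtures and Noninvasive Prenatal Paternity Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing two-SNP microhaplotype (SNP-SNP) marker
    panels used to detect the minor contributor of highly unbalanced,
    degraded DNA mixtures, in particular cell-free fetal DNA in maternal
    plasma for noninvasive prenatal paternity testing.  Classifies trio
    genotypes into informative-marker types, simulates allele-specific
    ARMS-PCR amplification with single-base-extension readout on a
    capillary-electrophoresis peak scale, models fragment-length
    distributions of heat-degraded genomic DNA and cell-free DNA and the
    resulting amplicon survival, computes panel-level population-genetics
    statistics (informativeness probabilities, Poisson-binomial
    informative-marker counts, effective number of alleles), and generates
    fully synthetic trio cohorts and plasma samples so every pipeline
    stage is testable without access to real specimens.  Ships a built-in
    15-locus SNP-SNP panel fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
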