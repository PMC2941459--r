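Package: stratpca
Title: Population-Level Principal Components for Detecting and Correcting
    Population Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Theoretical ("population") formulation of principal components
    analysis for structured genotype data. Reduces the n x n eigenproblem of
    the block genotype covariance induced by K populations to a K x K
    eigen-equation whose solutions are the axes of variation, estimates the
    underlying variance-covariance parameters (sigma^2, c, d) from genotype
    matrices, and corrects case-control association tests for population
    stratification by regressing out representative principal components,
    which is equivalent to subtracting population means of allele counts
    (popu-Eigenstrat). Includes a Balding-Nichols genotype simulator, Armitage
    and generalized Armitage trend tests, an Eigenstrat-style sample-PC
    correction, covariate adjustment, and readers and writers for the
    EIGENSTRAT geno/snp/ind text format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
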