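Package: rohmap
Title: Homozygosity Mapping of Recessive Disease Loci in Inbred Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Autozygosity mapping of autosomal-recessive disease loci in
    inbred populations such as closed dog breeds. Provides genotype
    input/output (VCF 4.x and PED/MAP), quality control, homozygote-excess
    inbreeding coefficients, principal component analysis, a standardized
    genomic relationship matrix, a univariate linear mixed model
    association scan with Wald tests, sliding-window run-of-homozygosity
    (ROH) detection with case/control autozygosity contrast and
    candidate-region delineation, recessive segregation and
    deleteriousness-based variant filtering, and genotype-by-status
    contingency statistics (relative risks, chi-square with continuity
    correction, exact tests).  A gene-drop pedigree simulator with a
    planted recessive causal variant generates fully synthetic test data
    so the whole pipeline is reproducible without cohort genotypes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
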