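Package: vtevar
Title: Family-Based Rare-Variant Discovery and Exact Association for
    Venous Thromboembolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and population-level assessment of rare thrombophilia
    variants. Implements a family-based filter cascade (shared heterozygotes,
    candidate-gene regions, nonsynonymous consequence, population allele
    frequency, deleteriousness annotation) over exome genotypes, and exact
    conditional 2x2 association statistics: minlike, central and Blaker
    two-sided p-values by hypergeometric enumeration, sample and conditional
    maximum-likelihood odds ratios, and test-inversion confidence intervals
    on the noncentral hypergeometric odds-ratio parameter. Includes
    linkage-disequilibrium r-squared on genotype dosages, covariate
    comparison and logistic confounding checks, subcohort homogeneity tests,
    a synthetic family/cohort generator for end-to-end testing, and a
    reproducible simulate-discover-associate pipeline with JSON reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
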