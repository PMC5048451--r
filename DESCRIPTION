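Package: chdrisk
Title: Genetic and Clinical Coronary Heart Disease Risk Modelling for
    Type 2 Diabetes Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for combining a 19-SNP weighted coronary heart disease
    (CHD) gene score with the UKPDS 10-year CHD risk engine for subjects
    with type 2 diabetes. Provides S4 containers and I/O for SNP panels and
    genotype call sets, risk-allele dosage reduction and weighted gene
    scores (with a recessive rule for NOS3 rs1799983), the UKPDS
    multiplicative-hazard risk equation with configuration-supplied
    coefficients, combination of genetic and clinical risk via odds-ratio
    to relative-risk conversion at a fixed baseline incidence, genotyping
    concordance quality control between two call sources, cohort-level
    baseline and gene-score-tertile statistics, and a seeded
    Hardy-Weinberg synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
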