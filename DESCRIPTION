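Package: rohclass
Title: Discovery of Unique Run-of-Homozygosity Genotypes with Unfavorable
    Effects on Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies unique run-of-homozygosity (ROH) genotype classes in
    SNP data with a sliding-window scan, screens them against an empirically
    calibrated phenotype threshold, estimates their effects against a non-ROH
    reference class with a pedigree-based animal mixed model (Henderson's
    mixed-model equations with the numerator relationship matrix), and
    controls the genome-wise false discovery rate by the Benjamini-Hochberg
    step-up rule.  Includes a gene-dropping simulator (pedigree, genotypes
    with mechanistically arising ROH, phenotypes with planted ROH-class
    effects) so the whole pipeline can be exercised and validated without
    external data, plus SNP quality control, pleiotropy grouping across
    traits, and interval-based gene annotation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
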