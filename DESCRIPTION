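Package: cacgrs
Title: Coronary Artery Calcification Genetic Risk Scores and Their Added
    Predictive Value for Coronary Artery Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing weighted genetic risk scores from
    PGS-Catalog-style scoring files and genotype dosages (VCF or plain
    dosage tables), with effect-allele harmonization and palindromic-SNP
    filtering; fitting nested logistic regression models of coronary
    artery disease with genotype principal-component adjustment,
    quantile-interval odds ratios and stratified reruns; beta regression
    of calcified-plaque area proportions with boundary squeezing; and a
    bootstrap train/test delta-AUC procedure quantifying the added
    predictive value of a score over traditional cardiovascular risk
    factors or over a second polygenic score. Includes a synthetic
    case-control cohort generator emulating clinical and autopsy cohort
    designs so that every pipeline stage is testable without access to
    private cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
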