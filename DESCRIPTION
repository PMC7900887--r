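Package: admixrisk
Title: Genetic Ancestry and Disease Risk Analysis for Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for quantifying the contribution of
    continental genetic ancestry to disease risk in two-way admixed
    case-control cohorts. Provides genotype input/output for VCF and PLINK
    text formats, sample- and variant-level quality control (missingness,
    heterozygosity, identity-by-descent relatedness pruning, exact
    Hardy-Weinberg and differential call-rate tests), LD pruning, principal
    component analysis of a genetic relationship matrix against a labeled
    reference panel, unsupervised two-way admixture estimation by
    expectation-maximization, local-ancestry inference at ancestry
    informative markers with a hidden Markov model and a covariate-adjusted
    admixture-mapping scan, a weighted polygenic risk score built from
    published glaucoma risk variants, and standardized logistic and linear
    association models. A synthetic-cohort generator with known ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
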