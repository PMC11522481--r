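Package: genoboost
Title: Sparse Polygenic Scores with Additive and Non-Additive Genetic Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sparse polygenic score models on individual-level genotype
    data by statistical boosting for binary disease outcomes. Each boosting
    iteration selects the single variant that most reduces a weighted
    least-squares approximation to the logistic loss and assigns it
    genotype-dependent scores with closed-form solutions, either constrained
    to be additive in allele dosage or free to capture genetic dominance
    (non-additive) effects. Includes PLINK 1 bed/bim/fam input and output,
    variant quality control, covariate pre-adjustment by logistic regression,
    cross-validated hyperparameter and model-type selection, predictive
    evaluation (covariate-adjusted pseudo-R2, top-percentile odds ratios,
    AUC, AUPRC), inference of each selected variant's mode of inheritance
    from its score triplet with a GWAS-based comparator, and a
    liability-threshold simulator for synthetic case-control cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
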