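Package: pathometa
Title: Random-Forest Metaprediction of Variant Pathogenicity from
    Categorical Functional-Impact Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds random-forest metapredictors of variant pathogenicity
    from the categorical calls of eight functional-impact predictors
    (FATHMM, SIFT, PolyPhen-2 HDIV/HVAR, PROVEAN, MutationAssessor,
    MutationTaster, LRT) as annotated in ClinVar-style VCF files by
    SnpSift/dbNSFP. Provides a seeded synthetic-variant generator, VCF
    ingestion, clinical-significance label grouping and complete-case
    filtering, four feature representations (label encoding, one-hot,
    multiple correspondence analysis, and a bottleneck autoencoder),
    grid-search tuning of random forests by out-of-bag error and
    cross-validated AUC, Gini-impurity feature importance, Naive Bayes
    and SVM baselines, and reclassification of variants of uncertain
    significance with a high-confidence probability threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    e1071,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
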