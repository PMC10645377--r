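Package: adcstratify
Title: Biomarker Stratification for DNA-Damaging Antibody-Drug Conjugates in Metastatic Prostate Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stratify metastatic prostate cancer models and clinical
    cohorts into predicted response classes for B7H3-targeted antibody-drug
    conjugates carrying a pyrrolobenzodiazepine (PBD) payload. Implements a
    normalized dose-response statistic (nAUC) with four-parameter logistic
    IC50 fitting, single-sample gene-set enrichment (ssGSEA-style) signature
    scoring with z-scaling and phenotype calling, TMM/ordered-quantile
    expression normalization with mixture-model SLFN11 expressor calling,
    immunohistochemistry H-score quantification, a composite genotype and
    biomarker decision engine, and a clinical-cohort stratification funnel.
    A synthetic-data generator reproduces the statistical structure of each
    input so the whole pipeline is testable without access to primary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    edgeR,
    mclust,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
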