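Package: caddsplice
Title: Genome-Wide Variant Deleteriousness Scoring with Deep-Learning Splice Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combined annotation-dependent variant effect scoring in the style
    of CADD v1.6 (CADD-Splice). Preprocesses SpliceAI and MMSplice submodel
    scores (site-aware masking, derived-allele swapping, class-oriented delta
    clipping, zero imputation with missingness indicators), expands annotated
    variants into the full 1029-column design matrix (annotation features,
    base-substitution and amino-acid-exchange indicators, missingness
    indicators, consequence-by-annotation feature crosses), fits a regularized
    logistic regression on proxy-benign versus proxy-deleterious labels, and
    converts raw scores to PHRED-like scaled scores. Includes the benchmark
    statistics used to evaluate splice-aware scores (precision-recall and ROC
    curves, allele-frequency enrichment with bootstrap confidence intervals,
    rank correlations), splice-disruption calling from percent-spliced-in
    measurements, and a synthetic-data generator with known generating weights
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    glmnet,
    data.table,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
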