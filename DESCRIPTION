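Package: tissueACP
Title: Tissue-Specific Anticancer Peptide Classification from Sequence Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking tissue-specific anticancer peptide (ACP)
    classifiers. Curates peptide records (alphabet and length filtering,
    keyword-based tissue annotation, IC50 standardisation, duplicate merging),
    encodes sequences into a 473-dimensional descriptor vector (amino acid
    composition, dipeptide composition, physicochemical property composition,
    and pseudo-amino acid composition), builds one-versus-rest tissue tasks
    with sequence-group-aware train/test splitting and cross-validation,
    trains and tunes five classifier families with algorithm-level class
    weighting, evaluates them with an eight-metric panel centred on the
    Matthews correlation coefficient and the area under the precision-recall
    curve, and aggregates tree-model feature importances by descriptor
    category. A synthetic cohort generator with planted composition signals
    makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
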