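Package: herbpair
Title: Screening Effective Herb Pairs from Prescription Networks and
    Biological Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for screening effective "coupled herbs"
    (herb pairs) from clinical prescription records. Builds a weighted herb
    co-occurrence network and extracts core herbs by iterated
    degree-coefficient thresholding; computes five pair-level effectiveness
    features (Manhattan co-prescription distance, Jaccard symptom similarity,
    summed compound oral bioavailability, random-walk-with-restart proximity
    of herb targets to disease genes on a confidence-weighted
    protein-interaction network, and Wang-method Gene Ontology semantic
    similarity); labels pairs by Apriori lift over the prescriptions; trains
    and compares five classifiers under stratified cross-validation with
    ROC/AUROC evaluation and Youden-cutoff screening; and characterises
    complementarity of the screened pairs by hypergeometric enrichment,
    quartile filtering, hierarchical clustering, and a cross-cluster exact
    test. Includes a seeded synthetic-data generator with planted effective
    pairs so that every stage is testable without access to private
    electronic medical records or external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    e1071,
    xgboost,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
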