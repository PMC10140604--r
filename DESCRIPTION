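Package: OncoAbstract
Title: Cross-Document Oncology Abstraction from Clinical Notes with Hierarchical Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registry-supervised abstraction of structured oncology attributes
    (tumor site, histology, coarse clinical and pathologic TNM staging) from a
    patient's full stream of clinical notes. Implements a hierarchical neural
    classifier (trainable transformer sentence encoder, bidirectional GRU
    contextualization across sentences, two-level attention over sentences and
    notes, softmax classification) trained under patient-level labels, a
    cancer case-finding scheme over patient-days with hard-negative
    self-supervision, ontology-lexicon and bag-of-words baselines,
    micro-averaged AUROC/AUPRC/accuracy evaluation with a disparate-impact
    fairness audit, attention-based rationale extraction with provenance, and
    a seeded synthetic clinical-corpus generator for end-to-end exercise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    glmnet,
    Matrix
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
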