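Package: deidr
Title: Hybrid De-Identification of Clinical Text with Learned
    Transformation Rules, Conditional Random Fields, and Stacked
    Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects protected health information (PHI) in clinical
    notes by sequence labeling over subword tokens. Combines a
    regex-seeded transformation-based error-driven rule learner, a
    linear-chain conditional random field with a unified feature set,
    and a stacked-generalization ensemble that selects final PHI
    candidates with a kernel classifier. Includes strict entity-level
    evaluation, standoff-annotation input/output, and a synthetic
    clinical-note generator with exact gold offsets so the whole
    pipeline can be exercised without access-restricted corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
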