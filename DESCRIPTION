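Package: dualsub
Title: Dual-Species Consensus Molecular Subtype Classification by
    Nearest-Template Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pathway-level classification of colorectal tumour expression
    profiles into the four consensus molecular subtypes (CMS), designed so
    that templates derived in human cohorts can be applied to mouse models.
    Implements single-sample gene-set enrichment (ssGSEA) scoring,
    nearest-template prediction with cosine correlation distances and
    permutation-based false-discovery rates, ortholog-aware translation of
    gene-level templates between species, and three template-derivation
    procedures (direct ortholog conversion of a gene template; Gene Ontology
    z-score selection; a four-collection t-test/LASSO assembly). A synthetic
    cohort generator with planted subtype structure and a paired ortholog
    namespace makes the whole system testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
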