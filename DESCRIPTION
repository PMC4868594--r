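Package: pcmfit
Title: Proteochemometric Modeling of Compound-Protein Interaction Activity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Proteochemometric (PCM) regression of bioactivity (pIC50) over
    compound-protein pairs, developed around inhibition of aromatase (CYP19A1)
    variants by steroidal and non-steroidal inhibitors. Compounds are encoded
    as substructure-fingerprint counts from a pluggable SMARTS dictionary,
    protein variants as position-specific three-component z-scale descriptors,
    and the interaction space as rowwise cross-terms between (and within)
    descriptor blocks. Thirteen canonical block combinations are fitted with
    random forest, partial least squares, ridge, RBF support-vector and
    Bayesian linear regression, and validated by K-means 80/20 partitioning,
    10-fold cross-validation, external prediction, leave-one-compound-out and
    leave-one-protein-out cross-validation, and Y-scrambling. Principal
    component analysis with Horn's parallel analysis and impurity-based
    feature-importance aggregation support exploration and interpretation.
    A seeded synthetic-data generator produces compound, variant and activity
    fixtures with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    ranger,
    glmnet,
    e1071,
    mixOmics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
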