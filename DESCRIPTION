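Package: dadsp
Title: Domain-Adaptive Deep Transfer Learning for Cancer Drug Sensitivity
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts half-maximal inhibitory concentrations (IC50) of
    anticancer compounds on cell lines from gene expression and hashed
    circular (Morgan) drug fingerprints, transferring knowledge from a
    large labeled source pharmacogenomic domain to a differently
    distributed target domain.  Implements two deep transfer strategies:
    an adversarial model with a gradient reversal layer and domain
    discriminator (DADSP-A), and a maximum-mean-discrepancy regularized
    stacked-autoencoder variant with staged parameter freezing (DADSP-B).
    Includes layer-wise stacked-autoencoder pretraining, the blind
    (leave-drug-and-cell-line-out) evaluation protocol, regression
    metrics, integrated-gradients gene attribution, a domain-confusion
    probe, and a synthetic source/target domain generator with a known
    response surface for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ChemmineOB,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
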