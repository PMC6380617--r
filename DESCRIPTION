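Package: ethacc
Title: Training-Set Accuracy Estimation and Optimization for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the accuracy of GBLUP/RR-BLUP genomic prediction for a
    given training set. Implements EthAcc, an estimator that plugs a causal-QTL
    model discovered by multilocus mixed-model (MLMM) forward-selection GWAS
    into the theoretical accuracy formula of the instrumental ridge-regression
    predictor, together with the classical CD- and PEV-based estimators, the
    CDmean training-set design criterion, hill-climbing training-set
    optimization with exchange moves, and a seeded generator of structured
    inbred-line panels with sparse additive QTL architectures for simulation
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
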