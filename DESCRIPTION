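Package: fluxmpi
Title: Predicting Metabolite-Protein Interactions from Model-Derived
    Metabolic Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts metabolite-protein interactions (MPIs) from features
    derived from constraint-based metabolic modelling combined with matched
    fluxomic and proteomic data. Estimates condition-specific flux
    distributions with parsimonious flux balance analysis (pFBA), computes
    flux sums as metabolite concentration proxies and eta values (the flux
    fraction unexplained by enzyme capacity) per reaction, builds
    pairwise-distance feature vectors for metabolite-reaction pairs,
    constructs gold-standard negative sets by several labelling strategies
    (PU-style potential-negative voting, interaction-score based, fingerprint
    Tanimoto, random control), trains Random Forest, Support Vector Machine
    and Multi-Layer Perceptron classifiers under balanced repeated
    cross-validation, and ranks metabolites by the number of reactions they
    are predicted to regulate. Includes a synthetic-data generator with a
    planted ground truth so the complete pipeline can be exercised and
    validated without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    e1071,
    nnet,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma,
    optparse
Config/testthat/edition: 3
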