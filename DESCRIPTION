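Package: nibopt
Title: Negative-Image-Based Docking Rescoring and Greedy Cavity-Model
    Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rescoring of rigid docking poses against cavity-based
    negative-image (NIB) models using Gaussian shape overlap and Hodgkin
    electrostatic-potential similarity, together with benchmark-driven
    greedy optimization of the models: single-atom pruning guided by
    virtual-screening enrichment metrics (ROC AUC with Wilcoxon standard
    error, enrichment factor at fixed decoy fractions, BEDROC). Includes
    TRIPOS MOL2 input/output for cavity models and multi-pose ligand
    libraries, seeded stratified training/test splits, a synthetic
    fixture generator with planted recoverable signal, and a command-line
    interface covering the train/test/validate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
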