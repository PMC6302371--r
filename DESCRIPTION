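Package: zernSIP
Title: Self-Interacting Protein Prediction from Sequence Profiles via
    Zernike Moments and Stacked LSTM Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts self-interacting proteins (homodimer-forming
    proteins) from sequence alone. Evolutionary profiles
    (position-specific scoring matrices from PSI-BLAST) are mapped onto
    the unit disk and summarised by rotation-invariant Zernike moment
    magnitudes, reduced by principal component analysis, and classified
    with a stacked long short-term memory network using peephole memory
    blocks, dropout regularisation, Nadam optimisation and early
    stopping. Includes dataset-curation rules for interaction-evidence
    tables, binary-classifier evaluation metrics (accuracy, sensitivity,
    specificity, precision, Matthews correlation coefficient, ROC/AUC),
    and a synthetic profile generator with a planted, recoverable class
    signal so the whole pipeline can be exercised without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
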