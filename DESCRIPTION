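Package: SpikeScreen
Title: Spiking Neural Network Virtual Screening from Molecular Fingerprints
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantized QSAR classification of small molecules with spiking
    neural networks. Binary molecular fingerprints (166-bit MACCS keys or
    hashed extended-connectivity fingerprints) are injected directly as input
    currents into networks of discrete-time leaky integrate-and-fire neurons;
    class membership is read out from output spike counts. Training uses
    surrogate-gradient backpropagation through time with a menu of standard
    optimizers, and models are evaluated by repeated nested cross-validation
    with random hyperparameter search, balanced accuracy and ROC AUC.
    Includes SMILES loading and standardization, Tanimoto similarity,
    minority-class oversampling, and a synthetic fingerprint generator for
    self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Cheminformatics, Classification, MachineLearning
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
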