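Package: electrum
Title: Electron Configuration-Based Fingerprints for Transition-Metal Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes mononuclear transition-metal complexes as fixed-length
    fingerprints built from hashed circular ligand substructures folded into a
    count vector (default 512 entries) and an 86-bit binary encoding of the
    coordinating metal's neutral ground-state electron configuration (598 bits
    combined). Includes a sanitization-free SMILES parser and writer, a
    complex-decomposition pipeline that strips counterions, deletes the metal
    from the molecular graph and recovers ligand SMILES together with the
    coordination number, exact Manhattan-distance k-nearest-neighbor search,
    baseline ligand-only and atomic-number encodings, a multilayer-perceptron
    cross-validation harness with scrambled-label controls and macro-averaged
    metrics, and a synthetic complex generator for self-contained evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
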