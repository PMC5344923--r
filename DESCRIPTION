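Package: pfkit
Title: Protection-Factor Prediction and Conformational Fitting for
    Hydrogen/Deuterium-Exchange Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hydrogen/deuterium-exchange (HDX) protection factors
    from protein structure using a phenomenological model driven by amide
    hydrogen-bond and heavy-atom contact counts, converts them into residue-
    and peptide-level deuterium-uptake curves via pseudo-first-order kinetics
    with sequence-predicted intrinsic exchange rates, scores the
    goodness-of-fit between structurally-derived and experimental HDX-NMR or
    HDX-MS data, selects best-fitting conformations from multi-model
    ensembles, and searches conformational space with a coarse-grained
    backbone-dihedral sampler whose move probabilities can be biased toward
    regions of large data discrepancy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
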