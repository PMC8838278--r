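Package: skinfuse
Title: Multiclass Skin Lesion Classification by Hybrid Feature Selection and Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multiclass dermoscopy image
    classification: hybrid local contrast enhancement based on absolute mean
    deviation and skewness, deep-feature extraction behind a pluggable backbone
    adapter (with a deterministic toy backbone for desk-scale work), best-feature
    selection by a hybrid whale optimization algorithm (wrapper, extreme learning
    machine error fitness) and by a fuzzy entropy-mutual information filter,
    fusion of the selected feature sets by multiset canonical correlation
    analysis with redundancy pruning, and extreme learning machine
    classification solved by the Moore-Penrose pseudoinverse. Synthetic
    generators for labeled feature matrices with known informative structure and
    for toy lesion images make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    png,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
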