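Package: oculotox
Title: QSAR Modeling of Eye Irritation and Corrosion Hazard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for building and validating classification models of
    ocular toxicity (GHS eye irritation and corrosion categories) from chemical
    structures. Covers structure curation (salt stripping, neutralization,
    chemotype normalization, removal of inorganics and mixtures, duplicate
    resolution), three descriptor spaces (2048-bit Morgan/circular
    fingerprints, 166 structural keys, whole-molecule physicochemical
    descriptors) with invariance and correlation filtering, similarity-driven
    under-sampling of imbalanced datasets, Random Forest and multi-descriptor
    read-across (MuDRA) classifiers, a k-nearest-neighbor Euclidean
    applicability domain, five-fold external cross-validation with
    Y-randomization, and a batch virtual-screening interface. Includes a
    synthetic structure generator with a planted substructure-activity signal
    so the full pipeline can be exercised without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
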