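Package: eemdSource
Title: EEMD-Based Source Localization of Event-Related EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Combines ensemble empirical mode decomposition (EEMD) of
    event-related EEG with standardized minimum-norm (sLORETA) source
    estimation. Multichannel trial epochs are decomposed into intrinsic
    mode functions, averaged into event-related modes, projected through a
    single-sphere lead field onto a volumetric source grid, and per-subject
    standardized dipole-energy maps are compared between two stimulus
    conditions with sign-flip max-statistic randomization tests. Includes a
    synthetic two-condition ERP study generator with dipolar P100/N200
    sources for validation, a minimal EDF reader/writer, and an end-to-end
    analysis pipeline with peak-cluster tabulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Electrophysiology, TimeCourse, Preprocessing, StatisticalMethod
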