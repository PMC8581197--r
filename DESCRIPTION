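Package: erdconnect
Title: Sensorimotor EEG Source Power and Directed Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for sensorimotor rhythm
    electroencephalography (EEG). Provides a forward simulator with a
    spherical-head leadfield and known oscillatory sources, preprocessing
    (band-pass filtering, variance-based bad-channel detection,
    spherical-spline repair, trial pruning, average referencing), multitaper
    cross-spectral estimation, an eLORETA weighted minimum-norm inverse
    solution with region-of-interest aggregation of Mu and Beta band power
    and event-related desynchronization (ERD) contrasts, isolated effective
    coherence (iCoh) directed connectivity from multivariate autoregressive
    models, and a statistical layer with paired t-tests, sign-flip
    max-statistic permutation correction, and behavior correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
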