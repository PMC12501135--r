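Package: eibdyn
Title: Excitation-Inhibition Balance Kinetics and Coactivation-Pattern Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline coupling sliding-window functional MRS estimates
    of the glutamate-plus-glutamine to GABA ratio (excitation-inhibition
    balance, EIB) with seed-based coactivation-pattern (CAP) dynamics of BOLD
    fMRI under graded working-memory load. Provides a synthetic-data generator
    for edited MEGA-PRESS spectra, Markov-driven BOLD volumes and n-back trial
    tables; simplified difference-spectrum peak fitting with water-referenced
    tissue-corrected quantification and z-score quality control; sliding-window
    concentration curves with outlier interpolation, baseline normalization and
    AUC; natural visibility-graph temporal features (mean out-degree and the
    in/out-degree Kullback-Leibler divergence); CAP decomposition with
    consensus selection of k, template matching, transition-graph temporal
    metrics and fMRS-matched persistence curves; partial least squares
    correlation with permutation and bootstrap inference; signal-detection
    behavioral scoring with log-linear d-prime and windowed performance AUC;
    and Kruskal-Wallis statistics with Dunn-style post hoc mean-rank
    differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
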