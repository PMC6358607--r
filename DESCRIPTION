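Package: hdde
Title: Closed-Loop High-Dimensional Differential Evolution for Discrete
    Media-Formulation Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Differential-evolution search over discrete factor-dose grids
    for cell-culture media formulation, run as a closed experiment loop.
    Selection is noise-aware (replicate responses compared by exact
    Wilcoxon rank-sum tests), every tested formulation is archived in a
    deduplicating evaluation library, a candidate solution set is
    maintained by competition against the best encountered and by a
    clearing (niching) mechanism, and mutation/crossover rates adapt on
    convergence. Ships pluggable in silico evaluators (a noisy Rosenbrock
    benchmark with an exact chain dynamic-programming grid oracle, and a
    synthetic log-linear cell-response landscape with left-censoring),
    formulation similarity metrics (Hamming and a dose-step Levenshtein
    equivalent), and post hoc quadratic response-surface analysis with
    left-censored imputation and FDR logworth volcano tables. A CSV
    propose/ingest interface supports lab-in-the-loop operation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
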