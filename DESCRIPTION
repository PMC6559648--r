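Package: nmtf
Title: Fast Optimization Methods for Non-Negative Matrix Tri-Factorization
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains non-negative matrix tri-factorization (NMTF) models
    X ~ U S t(V) under a squared Frobenius loss with four alternative
    optimization methods: multiplicative update rules (MUR), alternating
    least squares with non-negativity projection (ALS), projected gradients
    with adaptive step sizes (PG), and cyclic coordinate descent (COD).
    Provides dense and sparse computation paths, per-iteration convergence
    traces with divergence detection, multi-restart orchestration, a
    synthetic data generator with dense and sparse regimes, Matrix Market
    and delimited text input/output, a benchmarking harness comparing the
    methods, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
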