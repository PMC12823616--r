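Package: wavefdde
Title: Daubechies Wavelet Collocation for Fractional Delay Differential
    Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Solves systems of Caputo fractional-order delay differential
    equations by a hybrid Daubechies wavelet collocation scheme: compactly
    supported orthonormal scaling functions are evaluated by the cascade
    algorithm, Caputo derivatives and Riemann-Liouville integrals of the
    basis are assembled into operational (collocation) matrices by
    product-trapezoidal quadrature of the weakly singular kernel, and the
    delayed state is evaluated through a sparse shift (interpolation)
    matrix. Ships a delayed fractional SIR epidemic model of influenza
    transmission with reinfection as the flagship application, together
    with independent verification solvers (fractional Adams-Bashforth-
    Moulton predictor-corrector with delay, classical RK4 by the method of
    steps), Mittag-Leffler closed-form fixtures and manufactured-solution
    generators for convergence studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
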