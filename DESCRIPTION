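Package: pdbend
Title: Bending Symmetric Non-Positive-Definite Matrices to Positive-Definite
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Transforms symmetric non-positive-definite covariance and
    correlation matrices to positive-definite ("bending") by eigenvalue
    modification, so they can be inverted via Cholesky decomposition in
    multi-trait mixed models and selection indices. Implements weighted and
    unweighted iterative eigenvalue flooring (Jorjani, Klei and Emanuelson
    2003), replacement of negative eigenvalues by small positive values in
    descending order (Schaeffer 2014) including a weighted derivative, and
    correlation-matrix smoothing (Bock and Petersen 1988 style). Reports
    deviation and correlation diagnostics between the original and bent
    matrices, builds genomic relationship matrices (VanRaden 2008, method 1)
    from simulated genotype panels for ill-conditioned test cases, and ships
    a command-line interface over plain-text matrix files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
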