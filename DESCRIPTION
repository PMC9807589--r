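Package: canondx
Title: Nonlinear Canonical Decomposition Diagnostics for Feature Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short feature sequences (such as the fourteen PQRST
    amplitudes and intervals extracted from an electrocardiogram) by a
    maximum-likelihood rule built on a generalized nonlinear canonical
    decomposition. Each realization is transformed into empirically
    uncorrelated random coefficients by sequential orthogonalization of a
    monomial dictionary under sample mixed moments; class-conditional
    one-dimensional Parzen densities of the highest-order coefficient of each
    time block are multiplied to score classes. Linear and polynomial baseline
    criteria, a chi-squared coefficient-independence validation with
    model-order selection, a synthetic-sequence workbench with controlled
    first-, second- and third-order moment structure, CSV/JSON persistence and
    a command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
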