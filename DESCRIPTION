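Package: imprintr
Title: One-Shot Class Addition for Classifier Heads by Weight Imprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adds new classes to a trained linear classifier head from one
    (or K) activation vectors, without touching the backbone or the original
    weights. Implements Qi-style weight imprinting (unit-norm cosine head)
    and the DONE family of Hebbian-like imprinting rules that match the new
    weight row's mean, variance, or full empirical distribution (via
    quantile normalization against a per-rank-median reference multiset) to
    the original weights. Includes an interference/accuracy evaluation
    harness, principal-component analysis of weight rows with
    minimum-volume-enclosing-ellipsoid membership, a synthetic backbone
    generator emulating bell-shaped (transformer-like) and right-tailed
    (CNN-like) activation statistics, HDF5 and CSV head archives, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
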