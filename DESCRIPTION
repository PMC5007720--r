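Package: emgpr
Title: Myoelectric Movement Classification from Multi-Channel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline pattern-recognition toolkit for myoelectric
    (surface EMG) prosthesis control. Reads and writes multi-channel EMG
    recording sessions (a MAT-file v5 container compatible with common
    Matlab session structures, and a portable plain-text fixture format),
    extracts the four classic time-domain features (mean absolute value,
    waveform length, zero crossings, slope sign changes) from fixed sliding
    windows, and classifies individual and simultaneous hand/wrist
    movements across three degrees of freedom with linear discriminant
    analysis, softmax/logistic generalized linear models trained by
    iteratively reweighted least squares or scaled conjugate gradient, and
    multi-layer perceptrons trained by gradient descent or scaled conjugate
    gradient. Includes repeated stratified-split evaluation with Wilcoxon
    signed-rank comparison between methods, a hidden-unit sweep, and a
    seeded band-limited-noise EMG simulator so the whole pipeline runs with
    no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
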