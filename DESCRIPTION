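Package: deconsize
Title: Cell-Size-Aware Reference-Based Deconvolution of Bulk RNA-seq
Version: 0.1.0
Authors@R:
    person("deconsize", "developers", email = "deconsize@example.org",
           role = c("aut", "cre"))
Description: Estimates cell-type proportions in bulk RNA-seq samples from a
    single-cell derived signature matrix while correcting for cell-size
    differences via a scalar rescaling of the reference (Y = Z*S*P).
    Provides mean-ratio marker-gene selection, signature-matrix
    construction, cell-size scale-factor estimation from library sizes or
    imaging measurements, pseudobulk simulation with optional count noise,
    term-shuffle robustness experiments, non-negative least squares
    deconvolution on the probability simplex with a pluggable algorithm
    registry, and RMSE/bias/correlation evaluation, plus a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
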