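Package: spheroidABC
Title: Spatial Subclonal Interaction Inference from Spheroid Invasion Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying spatial interactions between tumour
    subclones from 3D spheroid invasion assays. Provides a stochastic 3D
    cellular-automaton model of spheroid growth and invasion for one or two
    clones advanced by Gillespie's stochastic simulation algorithm,
    mask-based invasion summary statistics (travelling-wave front and
    diffusion coefficients, convex-hull invaded area, cell density, and the
    area under the mono-culture-normalised area versus seeding-ratio curve),
    and a two-stage rejection approximate-Bayesian-computation pipeline that
    recovers per-clone proliferation and motility rates from mono-cultures
    and interaction strengths from co-cultures, with genetic-algorithm
    optimisation of summary-statistic weights, truncated-normal posterior
    fits, highest-density intervals and interaction classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
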