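Package: fretscape
Title: Fluorescence-Lifetime FRET Conformational Landscapes and DNA Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-correlated single-photon counting
    (TCSPC) fluorescence-lifetime FRET experiments on duplex DNA. Simulates
    multi-exponential photon-count decays with Poisson statistics, inverts
    decays into non-negative lifetime distributions by entropy-regularized
    least squares (maximum entropy method), decomposes distributions into
    Gaussian peaks whose areas are fractional conformational populations,
    and converts lifetimes to FRET efficiencies. Also computes DNA
    base-pair-step geometry descriptors (twist and untwist angles, bend
    angle, bend-direction and base-extrusion pseudo-dihedrals, hydrogen
    bonds, block-averaged uncertainties) from PDB coordinate ensembles, and
    includes an idealized duplex builder for generating fixtures with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    bio3d,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
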