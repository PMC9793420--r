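Package: rootpriming
Title: Multiscale Simulation of Lateral-Root Priming and Prebranch-Site Formation in the Arabidopsis Root Tip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic multiscale simulator of the Arabidopsis root tip
    that couples grid-level polar auxin transport (PIN efflux, AUX1/LAX3
    influx, wall and cytoplasmic diffusion, solved with an alternating
    direction semi-implicit scheme), per-cell gene-regulatory ordinary
    differential equations (AUX1, LAX3, YUCCA4, a generic auxin response
    factor with AUX/IAA quasi-steady-state signalling), a slow chromatin
    open-state variable that temporally integrates auxin signalling and
    gates positive feedback, TOLS2 peptide-mediated lateral inhibition, and
    cell growth, division and differentiation on a constant-sized domain.
    The package reproduces lateral-root priming oscillations at the start of
    the elongation zone and their conversion into stable prebranch sites,
    and provides named scenario presets for in-silico perturbation
    experiments, kymograph and cell-trace analysis, and event detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    rlang,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    purrr,
    jsonlite
Config/testthat/edition: 3
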