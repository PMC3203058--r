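Package: xicsim
Title: Lattice Polymer Monte Carlo of Conformation Switching and Symmetry
    Breaking at the X-Inactivation Center
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metropolis Monte Carlo simulation of two identical self-avoiding
    lattice polymers carrying typed binding regions that interact with two
    species of diffusing bridging molecules (a strings-and-binders model of
    the X-inactivation center). Provides state construction, an incremental
    energy function with valency-capped homotypic binding, local polymer and
    molecule move sets, order parameters for loop formation (P) and symmetry
    breaking (S), aggregate statistics, phase-diagram scans with transition
    line estimation, and calibration of lattice units to molar concentrations
    and real time via diffusion matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
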