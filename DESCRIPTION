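Package: ionpmf
Title: Nonequilibrium and Equilibrium Free-Energy Analysis of Multi-Ion
    Channel Permeation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Brownian-dynamics simulation of ions on model channel
    free-energy landscapes, step-wise harmonic pulling with Jarzynski
    ("useful work") free-energy estimation and per-ion decomposition,
    umbrella sampling with 1D/2D WHAM reconstruction of potentials of mean
    force including minima and bottleneck-path extraction, pair-coordinate
    occupancy analysis for detecting side-by-side ion blocking states, and
    the unit conversions relating work values to membrane potentials and
    forces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
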