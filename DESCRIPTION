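Package: thermoplan
Title: Treatment Planning for Magnetic Nanoparticle Hyperthermia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico treatment planning for magnetic nanoparticle
    hyperthermia of solid tumors. Solves the modified Pennes bioheat
    equation on a 3D cubic tissue domain with an explicit
    forward-time central-space finite-difference scheme, harmonic-mean
    face conductivities for piecewise-homogeneous media, zero-flux
    boundaries, and a Gaussian specific-absorption-rate (SAR) heat
    source for each nanoparticle injection. Quantifies thermal damage
    against the 43 degree Celsius ablation threshold and optimizes
    injection-site placement with a differential-evolution (best/1/bin)
    algorithm that fully ablates the tumor while minimizing damage to
    healthy tissue. Includes declarative scenario configuration (YAML),
    legacy-VTK export for ParaView, and command-line front-ends.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
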