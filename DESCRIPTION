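Package: dpdmeso
Title: Dissipative Particle Dynamics and Mesophase Structure Analysis for
    Ethoxylated Sulfate Surfactants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained dissipative particle dynamics (DPD) simulation and
    structural analysis of sodium lauryl ether sulfate (SLEnS) solutions.
    Provides the reduced-unit system and its mapping to SI units, construction
    of polydisperse ethoxylated surfactant topologies and simulation boxes at a
    target weight percentage, a DPD engine with a pairwise thermostat, harmonic
    bonds and angles, Slater-smeared electrostatics and Lees-Edwards shear,
    micelle identification with aggregation-number and radius-of-gyration
    statistics, lamellar d-spacing and hexagonal inter-rod spacing
    measurements, and closed-form enumeration of the periodicities allowed by
    periodic boundary conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
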