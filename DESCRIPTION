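Package: kapcg
Title: Coarse-Grained Simulation of Arginine-Rich Dipeptide Repeat
    Binding to Nuclear Transport Receptors
Version: 0.1.0
Authors@R:
    person("kapcg", "developers", email = "kapcg@example.org",
           role = c("aut", "cre"))
Description: One-bead-per-amino-acid (1BPA) implicit-solvent models of
    beta-karyopherin nuclear transport receptors and arginine-rich
    poly-PR dipeptide repeat proteins. Builds Calpha-bead models from
    PDB traces or from a synthetic HEAT-repeat solenoid generator, runs
    Langevin dynamics with Debye-screened electrostatics, cation-pi,
    excluded-volume and hydrophobic interactions under an elastic
    network that preserves receptor structure, and computes
    contact-map statistics: time-averaged contacts, binding
    probability, per-residue contact probabilities, region-resolved
    contact counts, overlap with native binding sites, and the
    correlation of contacts with net charge per residue (NCPR).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
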