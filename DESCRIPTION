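Package: kvperm
Title: Knock-On Permeation Analysis for Voltage-Gated Potassium Channel
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify potassium permeation through the pore of
    voltage-gated channels such as Kv2.1 from molecular-simulation
    trajectories: a geometric pore model built from anchor atoms, per-ion
    binding-site assignment (S0-S4, S_cav, cavity), detection of complete
    permeation events and concerted knock-on cycles, single-channel
    conductance, axial ion-density profiles, membrane-plane position
    histograms, and ligand-protein hydrophobic contact statistics for
    open-pore blockers (tetraethylammonium) and cavity-wall binders
    (RY785).  Includes a seeded kinetic Monte Carlo generator of synthetic
    knock-on trajectories for testing and calibration, evaluators for the
    restraint potentials commonly applied in such simulations
    (dihedral structure bias, flat-bottom confinements, knock-on pull),
    and transmembrane voltage/electric-field unit conversions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
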