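Package: dpdcnt
Title: Dissipative Particle Dynamics of Lipid Self-Assembly on Carbon Nanotubes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained dissipative particle dynamics (DPD) simulator and
    analysis toolkit for the self-assembly of dipalmitoylphosphatidylcholine
    (DPPC) on carbon nanotubes (CNTs). Provides the validated bead-spring
    parameterization of the 12-bead DPPC model and the eight-to-one CNT
    mapping, a system builder for nanotube/lipid/water boxes at reduced
    density three, an NPT DPD integrator with a momentum-conserving
    pairwise thermostat and anisotropic Berendsen pressure coupling, and
    observables for adsorption kinetics, aggregate clustering, cylindrical
    density profiles, tail-orientation order, and saturation surface
    density as a function of tube curvature. Trajectories are stored in
    extended-XYZ or a lossless full-precision archival text format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
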