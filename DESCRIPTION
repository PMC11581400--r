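Package: scaffoldflow
Title: Diffuse-Interface Simulation of Perfused Bioartificial Organ Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation of blood-plasma perfusion and oxygen
    transport in channeled poroelastic hydrogel scaffolds, as used in
    bioartificial pancreas design. Couples time-dependent Stokes flow in
    ultrafiltrate channels to Biot poroelasticity in the hydrogel through a
    diffuse-interface (phase-field) formulation with Beavers-Joseph-Saffman
    slip, then solves an advection-reaction-diffusion equation with
    Michaelis-Menten oxygen consumption on the frozen steady flow field.
    Channel-network architectures (straight, bifurcating, hexagonal, narrow
    straight, narrow zigzag) are generated programmatically under an
    equal-channel-area constraint, smoothed by an Allen-Cahn step on an
    adaptively refined triangulation, and ranked by the area of the hydrogel
    kept above the oxygen threshold for uninhibited insulin production.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
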