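Package: nucleomech
Title: Coupled Mechanochemical Simulation of Nuclear Deformation on
    Nanopillar Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Finite-element simulator of nuclear-envelope (NE) mechanics and
    mechanochemical signaling for cells on nanopillar arrays. The NE is an
    incompressible Mooney-Rivlin hyperelastic shell inflated by an osmotic
    pressure difference and compressed by a perinuclear actin cap, with
    substrate floor contact and nanopillar steric repulsion. Surface and
    volume reaction-transport of lamin A/C, nuclear pore complexes and
    YAP/TAZ is advanced on the deforming geometry by an implicit-diffusion /
    multiplicative-dilution splitting, bidirectionally coupled to the
    mechanics through lamin-dependent stiffness and stretch-gated nuclear
    import. Includes quarter-shell mesh generation, a closed-form
    thick-sphere inflation oracle, pitch-sweep drivers, and metrics such as
    lower-NE stretch, membrane tension, YAP/TAZ nuclear-to-cytosolic ratio
    and force per lamin subunit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
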