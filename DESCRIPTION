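Package: effham
Title: Symmetry-Adapted Learning of Effective Single-Particle Hamiltonians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts effective single-particle Hamiltonians of molecules and
    periodic solids with symmetry-adapted linear models, and trains them either
    directly against reference matrix elements or indirectly against derived
    quantum-mechanical observables (molecular-orbital energies, dipole moments,
    polarizabilities, Mayer bond orders, band energies) through a differentiable
    property layer with analytic adjoints. Hamiltonian blocks are coupled into
    O(3) irreducible components with real Clebsch-Gordan coefficients and
    modeled on equivariant two-center descriptors. Includes upscaled training,
    where a small-basis effective Hamiltonian reproduces large-basis targets,
    eigenbasis-alignment and projection diagnostics, Bloch-sum band structures
    with delta-learning, and a self-contained synthetic reference engine
    (closed-form Gaussian integrals and extended-Hueckel Hamiltonians in paired
    toy bases) so that every component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
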