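Package: rpdyn
Title: Path-Integral and Ring-Polymer Molecular Dynamics for Dissociative
    Photodetachment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantum thermal sampling and real-time dynamics for anion
    photodetachment studies. Implements the classical-isomorphism
    ring-polymer Hamiltonian, massive Nose-Hoover-chain thermostatted
    path-integral molecular dynamics (PIMD) for sampling the anionic
    quantum Boltzmann density, vertical electron detachment, thermostat-free
    ring-polymer molecular dynamics (RPMD) on the neutral surface, and the
    derived observables: semiclassical photoelectron spectra,
    photoelectron-photofragment coincidence spectra, fragment
    kinetic-energy release, and dihedral-based cis/trans product
    classification. On-the-fly electronic structure is replaced by a
    pluggable potential-surface contract with analytic model surfaces,
    including a centroid second-order Taylor expansion of the bead forces,
    so the whole workflow runs and is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
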