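Package: polyenedyn
Title: Mixed Quantum-Classical DMRG Dynamics of Polyene Photoexcited States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the internal-conversion dynamics of photoexcited linear
    polyenes and carotenoids with the extended Hubbard-Peierls (UV-Peierls)
    model. Electrons are propagated with adaptive time-dependent DMRG
    (Suzuki-Trotter link propagators on a matrix-product state), nuclei with
    damped-velocity-Verlet Ehrenfest dynamics on Hellmann-Feynman forces.
    Includes a full exact-diagonalization oracle for short chains, static DMRG
    with multi-state targeting and geometry relaxation, Lanczos-DMRG transient
    absorption spectra, adiabatic/diabatic population analysis with a
    Landau-Zener crossover scan, and projected-gradient fitting of
    symmetry-breaking site potentials to target charge densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
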