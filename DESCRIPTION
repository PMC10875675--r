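Package: edff
Title: Electron-Density Pair Force Field with Laplacian-Order
    Exchange-Correlation Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Intermolecular pair interaction energies computed from frozen,
    Gaussian-expanded monomer electron densities.  A closed-form Coulomb
    ("naive") model between the two frozen densities and nuclei is corrected
    by an exchange-correlation series built from iterated Laplacians of the
    densities, whose weights are calibrated against reference interaction
    energies by exact linear least squares or a seeded genetic-algorithm plus
    BFGS optimizer.  Includes rigid-monomer dimer scan generators for water
    and molecular oxygen, a synthetic reference-energy generator, radial
    density fitting with s-type Gaussians, Mulliken-charge population
    scaling, and plain-text readers and writers for geometries, density
    parameter tables, coefficient files and reference-energy sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
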