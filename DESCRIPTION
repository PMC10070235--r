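Package: diabex
Title: Diabatic Exciton and Charge-Transfer Model Hamiltonians for Chromophore Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and solves six-state diabatic model Hamiltonians for
    chromophore dimers such as stacked chlorophyll pairs. Locally excited (Qy, Qx)
    and charge-transfer (A+B-, A-B+) basis states are assembled block by block from
    fragment-level quantities: generalized fragment-orbital (FODFT) couplings from
    orbital energies and non-orthogonal overlap matrices, Marcus-type two-state
    charge-transfer energetics with the correct -1/R long-range interaction,
    Forster-type Coulomb couplings from discrete transition charges, and a discrete
    reaction field (DRF) environment of permanent charges with self-consistently
    induced dipoles. A synthetic Slater-orbital electronic-structure backend makes
    every matrix element exercisable without an external quantum-chemistry engine,
    and snapshot-ensemble utilities summarise energies, couplings and environment
    shifts across molecular-dynamics-like frame sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
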