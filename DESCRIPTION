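Package: caf1arch
Title: Quantitative Biophysics of CAF-1-Histone Chaperone Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for probing the architecture of the CAF-1
    histone chaperone bound to H3/H4: equilibrium binding isotherms with
    ligand depletion and fluorophore-quench correction, coupled
    chaperone/histone-tetramerization equilibria, acceptor-enhancement FRET
    spectral extraction, electrophoretic mobility shift (EMSA) tetrasome
    quantification, differential hydrogen/deuterium exchange (HX-MS)
    analysis, cross-linking mass-spectrometry (XL-MS) filtering and
    structural validation, and structural metrics (solvent-accessible
    surface area, buried interfaces, rigid-body superposition).
    Seed-controlled synthetic-data generators emulate each experiment so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
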