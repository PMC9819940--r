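Package: azospectra
Title: Ensemble Simulation of Azobenzene Photoswitch Absorption Band Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds full electronic absorption band shapes for azobenzene-derived
    photoswitches from ensembles of per-snapshot excited-state calculations, using
    oscillator-strength over excitation-energy (f/dE) weighted histograms. Provides
    a JSON-Lines interchange format for snapshot excitation records, multi-frame
    XYZ trajectory reading and dihedral-distribution diagnostics of the E/Z azo
    configuration and phenyl-ring inclination, LCAO atomic-orbital weight
    decomposition of the orbitals involved in the excitation, molecular-orbital
    energy statistics and their correlation with free-halide valence-orbital
    energies, and a synthetic snapshot generator that emulates the statistical
    structure of a QM/MM molecular-dynamics plus TD-DFT data stream for the
    tetra-ortho-halogenated azobenzene series (X = H, F, Cl, Br).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
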